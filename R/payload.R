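# Intermediate-statistic payloads: the only objects that ever cross a site
# boundary. A payload is a named set of numeric components (scalars,
# vectors, matrices) plus a manifest (kind, site id, iteration index, spec
# digest). Components are summary-level by construction: moment matrices,
# score vectors, per-event-time risk-set sums, prediction-bin counts.

# How each component of each payload kind combines across sites:
#   additive   - elementwise sum (the common case for sufficient statistics)
#   concat     - rows stacked (prediction bins; each row is already a
#                summary over >= 1 patients)
#   identical  - must be equal at every site (the shared event-time grid)
#   grid_count - union-merge of (times, tie counts) pairs
payload_schemas <- list(
  linear_intermediates = list(
    components = c("n", "xtx", "xty", "yty", "sum_y"),
    rule = c(n = "additive", xtx = "additive", xty = "additive",
             yty = "additive", sum_y = "additive")),
  linear_diagnostics = list(
    components = c("n", "sse", "sum_y", "yty"),
    rule = c(n = "additive", sse = "additive", sum_y = "additive",
             yty = "additive")),
  glm_iteration = list(
    components = c("n", "gradient", "information", "loglik"),
    rule = c(n = "additive", gradient = "additive",
             information = "additive", loglik = "additive")),
  glm_diagnostics = list(
    components = c("n", "gradient", "information", "loglik", "bins"),
    rule = c(n = "additive", gradient = "additive",
             information = "additive", loglik = "additive",
             bins = "concat")),
  event_grid = list(
    components = c("n", "times", "d"),
    rule = c(n = "additive", times = "grid_count", d = "grid_count")),
  cox_iteration = list(
    components = c("n", "times", "S0", "S1", "S2",
                   "d", "s", "S0D", "S1D", "S2D"),
    rule = c(n = "additive", times = "identical", S0 = "additive",
             S1 = "additive", S2 = "additive", d = "additive",
             s = "additive", S0D = "additive", S1D = "additive",
             S2D = "additive")),
  cox_diagnostics = list(
    components = c("n", "times", "S0", "S1", "S2",
                   "d", "s", "S0D", "S1D", "S2D"),
    rule = c(n = "additive", times = "identical", S0 = "additive",
             S1 = "additive", S2 = "additive", d = "additive",
             s = "additive", S0D = "additive", S1D = "additive",
             S2D = "additive"))
)

new_payload <- function(kind, site_id, iteration, digest, components) {
  schema <- payload_schemas[[kind]]
  if (is.null(schema))
    stop_dranet("unknown payload kind '%s'", kind,
                class = "dranet_protocol_error")
  missing <- setdiff(schema$components, names(components))
  if (length(missing))
    stop_dranet("payload kind '%s': missing component(s) %s", kind,
                paste(missing, collapse = ", "),
                class = "dranet_protocol_error")
  extra <- setdiff(names(components), schema$components)
  if (length(extra))
    stop_dranet("payload kind '%s': undeclared component(s) %s", kind,
                paste(extra, collapse = ", "),
                class = "dranet_protocol_error")
  components <- lapply(components[schema$components], function(v) {
    storage.mode(v) <- "double"        # the wire format carries doubles
    v
  })
  structure(list(kind = kind, site_id = as.character(site_id),
                 iteration = as.integer(iteration),
                 digest = as.character(digest),
                 components = components),
            class = "dra_payload")
}

#' @export
print.dra_payload <- function(x, ...) {
  cat(sprintf("<dra_payload %s | site %s | iteration %d | digest %s>\n",
              x$kind, x$site_id, x$iteration, x$digest))
  for (nm in names(x$components)) {
    v <- x$components[[nm]]
    dim_str <- if (is.matrix(v)) paste(dim(v), collapse = "x")
               else as.character(length(v))
    cat(sprintf("  %-12s [%s]\n", nm, dim_str))
  }
  invisible(x)
}

component_dims <- function(v) {
  if (is.matrix(v)) c(nrow(v), ncol(v)) else c(length(v), 1L)
}

#' Write a payload to a text file
#'
#' Payload files are plain text: a format tag line, a one-line JSON manifest
#' (kind, site id, iteration, spec digest, component shapes), then one
#' delimited numeric block per component rendered with 17 significant
#' digits so that every double round-trips bit-exactly. A terminating
#' `@end` marker makes truncation detectable.
#'
#' @param payload A payload as produced by the site-side computations.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [read_payload()]
#' @export
write_payload <- function(payload, path) {
  stopifnot(inherits(payload, "dra_payload"))
  manifest <- jsonlite::toJSON(list(
    kind = payload$kind, site_id = payload$site_id,
    iteration = payload$iteration, digest = payload$digest,
    components = lapply(payload$components, function(v) {
      d <- component_dims(v)
      list(nrow = d[1L], ncol = d[2L])
    })), auto_unbox = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#dranet-payload v1", con)
  writeLines(as.character(manifest), con)
  for (nm in names(payload$components)) {
    v <- payload$components[[nm]]
    d <- component_dims(v)
    writeLines(sprintf("@%s %d %d", nm, d[1L], d[2L]), con)
    if (d[1L] > 0L) {
      m <- if (is.matrix(v)) v else matrix(v, ncol = 1L)
      lines <- apply(m, 1L, function(r) paste(fmt_real(r), collapse = "\t"))
      writeLines(lines, con)
    }
  }
  writeLines("@end", con)
  invisible(path)
}

#' Read a payload written by [write_payload()]
#'
#' Validates the format tag, manifest, every declared component block, and
#' the terminating marker; a truncated or malformed file raises a parse
#' error naming the offending component rather than returning partial data.
#'
#' @param path File path to read.
#' @return A payload object.
#' @export
read_payload <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e)
                      stop_dranet("cannot read payload file '%s': %s", path,
                                  conditionMessage(e),
                                  class = "dranet_parse_error"))
  if (length(lines) < 3L || lines[1L] != "#dranet-payload v1")
    stop_dranet("'%s' is not a dranet payload file", path,
                class = "dranet_parse_error")
  manifest <- tryCatch(jsonlite::fromJSON(lines[2L], simplifyVector = FALSE),
                       error = function(e)
                         stop_dranet("'%s': malformed manifest: %s", path,
                                     conditionMessage(e),
                                     class = "dranet_parse_error"))
  for (f in c("kind", "site_id", "iteration", "digest", "components"))
    if (is.null(manifest[[f]]))
      stop_dranet("'%s': manifest missing field '%s'", path, f,
                  class = "dranet_parse_error")
  comps <- list()
  i <- 3L
  for (nm in names(manifest$components)) {
    decl <- manifest$components[[nm]]
    nr <- as.integer(decl$nrow); nc <- as.integer(decl$ncol)
    header <- sprintf("@%s %d %d", nm, nr, nc)
    if (i > length(lines) || lines[i] != header)
      stop_dranet("'%s': expected block header '%s' at line %d", path,
                  header, i, class = "dranet_parse_error")
    i <- i + 1L
    if (nr > 0L) {
      if (i + nr - 1L > length(lines))
        stop_dranet("'%s': component '%s' truncated (expected %d rows)",
                    path, nm, nr, class = "dranet_parse_error")
      block <- lines[i:(i + nr - 1L)]
      vals <- strsplit(block, "\t", fixed = TRUE)
      if (any(lengths(vals) != nc))
        stop_dranet("'%s': component '%s' has a row with wrong width", path,
                    nm, class = "dranet_parse_error")
      num <- suppressWarnings(as.numeric(unlist(vals, use.names = FALSE)))
      if (anyNA(num))
        stop_dranet("'%s': component '%s' contains non-numeric data", path,
                    nm, class = "dranet_parse_error")
      m <- matrix(num, nrow = nr, ncol = nc, byrow = TRUE)
      comps[[nm]] <- if (nc == 1L) drop_to_vector(m) else m
      i <- i + nr
    } else {
      comps[[nm]] <- if (nc == 1L) numeric(0) else
        matrix(numeric(0), nrow = 0L, ncol = nc)
    }
  }
  if (i > length(lines) || lines[i] != "@end")
    stop_dranet("'%s': missing '@end' marker - file truncated?", path,
                class = "dranet_parse_error")
  new_payload(manifest$kind, manifest$site_id, manifest$iteration,
              manifest$digest, comps)
}

drop_to_vector <- function(m) as.numeric(m[, 1L])

#' Aggregate payloads across sites
#'
#' Combines one payload per site into the network-wide payload the analysis
#' center operates on. Additive components (moment matrices, gradients,
#' information matrices, risk-set sums, log-likelihood contributions, row
#' counts) are summed elementwise; prediction-bin tables are stacked;
#' event-time grids are union-merged with tie counts summed at shared
#' times. Payloads are combined in sorted site-id order so the result is
#' independent of arrival order.
#'
#' @param payloads List of payloads sharing kind, iteration, spec digest,
#'   and component shapes.
#' @return A single aggregated payload with `site_id = "ALL"`.
#' @export
aggregate_payloads <- function(payloads) {
  stopifnot(is.list(payloads), length(payloads) >= 1L)
  lapply(payloads, function(p) stopifnot(inherits(p, "dra_payload")))
  ord <- order(vapply(payloads, `[[`, "", "site_id"))
  payloads <- payloads[ord]
  first <- payloads[[1L]]
  for (p in payloads[-1L]) {
    if (p$kind != first$kind)
      stop_dranet("payload kind mismatch: '%s' vs '%s'", p$kind, first$kind,
                  class = "dranet_protocol_error")
    if (p$iteration != first$iteration)
      stop_dranet("iteration mismatch: site %s is at %d, expected %d",
                  p$site_id, p$iteration, first$iteration,
                  class = "dranet_protocol_error")
    if (p$digest != first$digest)
      stop_dranet("spec digest mismatch at site %s", p$site_id,
                  class = "dranet_protocol_error")
  }
  schema <- payload_schemas[[first$kind]]
  rule <- schema$rule
  out <- first$components
  if (any(rule == "grid_count")) {
    # union-merge the (times, d) pairs across all payloads at once
    all_t <- unlist(lapply(payloads, function(p) p$components$times))
    all_d <- unlist(lapply(payloads, function(p) p$components$d))
    ut <- sort(unique(all_t))
    out$times <- ut
    out$d <- as.numeric(rowsum(all_d, match(all_t, ut)))
    out$n <- sum(vapply(payloads, function(p) p$components$n, 0))
    return(new_payload(first$kind, "ALL", first$iteration, first$digest, out))
  }
  for (p in payloads[-1L]) {
    for (nm in schema$components) {
      a <- out[[nm]]; b <- p$components[[nm]]
      r <- rule[[nm]]
      if (r == "additive") {
        if (!identical(component_dims(a), component_dims(b)))
          stop_dranet("component '%s': shape mismatch at site %s", nm,
                      p$site_id, class = "dranet_protocol_error")
        out[[nm]] <- a + b
      } else if (r == "concat") {
        if (ncol(as_matrix(b)) != ncol(as_matrix(a)))
          stop_dranet("component '%s': width mismatch at site %s", nm,
                      p$site_id, class = "dranet_protocol_error")
        out[[nm]] <- rbind(as_matrix(a), as_matrix(b))
      } else if (r == "identical") {
        if (!identical(a, b))
          stop_dranet("component '%s' must be identical across sites; site %s differs",
                      nm, p$site_id, class = "dranet_protocol_error")
      }
    }
  }
  new_payload(first$kind, "ALL", first$iteration, first$digest, out)
}

as_matrix <- function(v) if (is.matrix(v)) v else matrix(v, ncol = 1L)
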
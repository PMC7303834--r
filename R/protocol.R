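# File-based master-worker protocol. One analysis-center node and k
# data-partner nodes exchange files through per-site transfer directories:
#
#   workdir/to_<site>/    directives from the center (partner inbox)
#   workdir/from_<site>/  payloads from the partner (partner outbox)
#
# Every substantive file is written completely before a zero-byte
# `<name>.trigger` marker is created, so the appearance of a trigger
# guarantees a complete file. Directives are numbered by a monotone
# sequence; partners process them in order and ignore (with a log entry)
# anything stale. Only directive, payload, trigger, acknowledgement,
# error, and timing-log files ever appear in a transfer directory —
# never individual-level data.

dir_to <- function(workdir, site) file.path(workdir, paste0("to_", site))
dir_from <- function(workdir, site) file.path(workdir, paste0("from_", site))

protocol_dirs <- function(workdir, site_ids) {
  for (s in site_ids) {
    dir.create(dir_to(workdir, s), recursive = TRUE, showWarnings = FALSE)
    dir.create(dir_from(workdir, s), recursive = TRUE, showWarnings = FALSE)
  }
  invisible(workdir)
}

write_with_trigger <- function(writer, path) {
  writer(path)
  file.create(paste0(path, ".trigger"))
  invisible(path)
}

directive_path <- function(workdir, site, seq)
  file.path(dir_to(workdir, site), sprintf("directive_%04d.json", seq))

payload_path <- function(workdir, site, seq)
  file.path(dir_from(workdir, site), sprintf("payload_%04d_%s.dra", seq, site))

write_directive <- function(directive, path) {
  txt <- jsonlite::toJSON(directive[!vapply(directive, is.null, TRUE)],
                          auto_unbox = TRUE, digits = I(17))
  write_with_trigger(function(p) writeLines(as.character(txt), p), path)
}

read_directive <- function(path) {
  d <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                   simplifyVector = TRUE),
                error = function(e)
                  stop_dranet("malformed directive '%s': %s", path,
                              conditionMessage(e),
                              class = "dranet_parse_error"))
  for (f in c("seq", "instruction", "iteration", "family", "digest"))
    if (is.null(d[[f]]))
      stop_dranet("directive '%s' missing field '%s'", path, f,
                  class = "dranet_parse_error")
  d
}

# Read a payload uploaded by a partner, attributing parse failures to the
# node and protocol round they came from.
center_read_payload <- function(path, node, seq) {
  tryCatch(read_payload(path), dranet_parse_error = function(e)
    stop_dranet("payload from node '%s' (round %d) is corrupt: %s",
                node, seq, conditionMessage(e),
                class = c("dranet_parse_error", "dranet_protocol_error")))
}

now_ts <- function() as.numeric(Sys.time())

log_record <- function(node, node_class, iteration, step, start, end) {
  data.frame(node = node, node_class = node_class,
             iteration = as.integer(iteration), step = step,
             start = start, end = end, stringsAsFactors = FALSE)
}

append_log_file <- function(path, rec) {
  line <- jsonlite::toJSON(as.list(rec[1L, ]), auto_unbox = TRUE,
                           digits = I(17))
  cat(as.character(line), "\n", sep = "", file = path, append = TRUE)
}

read_log_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}

# ---------------------------------------------------------------------
# Partner side

partner_state <- function(workdir, site_id, env, spec) {
  list2env(list(workdir = workdir, site_id = site_id, env = env,
                spec = spec, last_seq = 0L, done = FALSE,
                log_path = file.path(dir_from(workdir, site_id),
                                     sprintf("log_%s.jsonl", site_id))),
           envir = new.env(parent = emptyenv()))
}

# Process at most one pending directive. Returns TRUE if one was handled.
partner_step <- function(st) {
  if (st$done) return(FALSE)
  inbox <- dir_to(st$workdir, st$site_id)
  trig <- list.files(inbox, pattern = "^directive_\\d+\\.json\\.trigger$")
  if (!length(trig)) return(FALSE)
  files <- sort(sub("\\.trigger$", "", trig))
  seqs <- as.integer(sub("^directive_(\\d+)\\.json$", "\\1", files))
  # a trigger for an already-processed round is stale (a re-delivery):
  # log it and delete the trigger, leaving the directive file for audit
  for (i in which(seqs <= st$last_seq)) {
    t0 <- now_ts()
    append_log_file(st$log_path, log_record(st$site_id, "partner", seqs[i],
                                            "stale_ignored", t0, t0))
    unlink(file.path(inbox, paste0(files[i], ".trigger")))
  }
  pending <- which(seqs > st$last_seq)
  if (!length(pending)) return(FALSE)
  i <- pending[1L]
  seq <- seqs[i]
  path <- file.path(inbox, files[i])
  unlink(paste0(path, ".trigger"))     # claim the directive
  t0 <- now_ts()
  directive <- tryCatch(read_directive(path), error = function(e) e)
  t1 <- now_ts()
  if (inherits(directive, "error")) {
    err_path <- file.path(dir_from(st$workdir, st$site_id),
                          sprintf("error_%04d_%s.json", seq, st$site_id))
    write_with_trigger(function(p) writeLines(as.character(
      jsonlite::toJSON(list(site_id = st$site_id, seq = seq,
                            message = conditionMessage(directive)),
                       auto_unbox = TRUE)), p), err_path)
    st$last_seq <- seq
    return(TRUE)
  }
  append_log_file(st$log_path, log_record(st$site_id, "partner",
                                          directive$iteration, "download",
                                          t0, t1))
  if (directive$instruction == "stop") {
    ack <- file.path(dir_from(st$workdir, st$site_id),
                     sprintf("ack_%04d_%s.json", seq, st$site_id))
    write_with_trigger(function(p) writeLines(as.character(
      jsonlite::toJSON(list(site_id = st$site_id, seq = seq,
                            status = "stopped"), auto_unbox = TRUE)), p),
      ack)
    st$done <- TRUE
    st$last_seq <- seq
    return(TRUE)
  }
  t2 <- now_ts()
  payload <- tryCatch(partner_compute(directive, st$env),
                      error = function(e) e)
  t3 <- now_ts()
  if (inherits(payload, "error")) {
    err_path <- file.path(dir_from(st$workdir, st$site_id),
                          sprintf("error_%04d_%s.json", seq, st$site_id))
    write_with_trigger(function(p) writeLines(as.character(
      jsonlite::toJSON(list(site_id = st$site_id, seq = seq,
                            message = conditionMessage(payload)),
                       auto_unbox = TRUE)), p), err_path)
    st$last_seq <- seq
    return(TRUE)
  }
  append_log_file(st$log_path, log_record(st$site_id, "partner",
                                          directive$iteration, "compute",
                                          t2, t3))
  out <- payload_path(st$workdir, st$site_id, seq)
  t4 <- now_ts()
  write_with_trigger(function(p) write_payload(payload, p), out)
  t5 <- now_ts()
  append_log_file(st$log_path, log_record(st$site_id, "partner",
                                          directive$iteration, "upload",
                                          t4, t5))
  st$last_seq <- seq
  TRUE
}

#' Run a data-partner node of the file-exchange protocol
#'
#' Blocks, polling its inbox for directive trigger files, computing the
#' requested summary-level intermediates on the local data, and uploading
#' payload files (each followed by its trigger) until a stop directive
#' arrives. Individual-level rows are never written to the outbox.
#'
#' @param workdir Shared protocol directory.
#' @param site_id This partner's identifier.
#' @param data The site's individual-level data frame (or a path to its
#'   CSV file).
#' @param spec The shared [dra_spec()].
#' @param poll Poll interval in seconds.
#' @param timeout Seconds of silence after which the partner gives up.
#' @return Invisibly, the number of directives processed.
#' @export
dra_run_partner <- function(workdir, site_id, data, spec, poll = 0.05,
                            timeout = 300) {
  if (is.character(data)) data <- utils::read.csv(data,
                                                  stringsAsFactors = FALSE)
  protocol_dirs(workdir, site_id)
  st <- partner_state(workdir, site_id, site_env(data, spec, site_id), spec)
  handled <- 0L
  last_activity <- now_ts()
  while (!st$done) {
    if (partner_step(st)) {
      handled <- handled + 1L
      last_activity <- now_ts()
    } else {
      if (now_ts() - last_activity > timeout)
        stop_dranet("partner %s: no directive for %g s, giving up",
                    site_id, timeout, class = "dranet_timeout_error")
      Sys.sleep(poll)
    }
  }
  invisible(handled)
}

# ---------------------------------------------------------------------
# Center side

# Build the collect() closure used by the center algorithm. If
# `step_fns` is non-NULL (cooperative single-process mode) the partner
# states are advanced inside the wait loop; otherwise the center purely
# polls the filesystem and real partner processes do the work.
center_collect_factory <- function(workdir, site_ids, spec, step_fns = NULL,
                                   poll = 0.02, timeout = 120,
                                   log_env = NULL) {
  seq_counter <- new.env(parent = emptyenv())
  seq_counter$seq <- 0L
  seq_counter$last_collect_end <- NA_real_

  function(directive) {
    seq_counter$seq <- seq_counter$seq + 1L
    seq <- seq_counter$seq
    directive$seq <- seq
    t_up0 <- now_ts()
    if (!is.na(seq_counter$last_collect_end) && !is.null(log_env))
      log_env$records[[length(log_env$records) + 1L]] <-
        log_record("center", "center", directive$iteration, "compute",
                   seq_counter$last_collect_end, t_up0)
    for (s in site_ids)
      write_directive(directive, directive_path(workdir, s, seq))
    t_up1 <- now_ts()
    if (!is.null(log_env))
      log_env$records[[length(log_env$records) + 1L]] <-
        log_record("center", "center", directive$iteration, "upload",
                   t_up0, t_up1)
    if (directive$instruction == "stop") {
      seq_counter$last_collect_end <- now_ts()
      return(invisible(NULL))
    }
    want <- stats::setNames(payload_path(workdir, site_ids, seq), site_ids)
    deadline <- now_ts() + timeout
    repeat {
      if (!is.null(step_fns)) for (f in step_fns) f()
      have <- file.exists(paste0(want, ".trigger"))
      errs <- file.exists(file.path(dir_from(workdir, site_ids),
                                    sprintf("error_%04d_%s.json", seq,
                                            site_ids)))
      if (any(errs)) {
        msgs <- vapply(which(errs), function(i) {
          e <- jsonlite::fromJSON(readLines(
            file.path(dir_from(workdir, site_ids[i]),
                      sprintf("error_%04d_%s.json", seq, site_ids[i])),
            warn = FALSE))
          sprintf("%s: %s", site_ids[i], e$message)
        }, "")
        stop_dranet("partner error(s) in round %d: %s", seq,
                    paste(msgs, collapse = "; "),
                    class = "dranet_protocol_error")
      }
      if (all(have)) break
      if (now_ts() > deadline)
        stop_dranet("timed out waiting for round %d; missing node(s): %s",
                    seq, paste(site_ids[!have], collapse = ", "),
                    class = "dranet_timeout_error")
      if (is.null(step_fns)) Sys.sleep(poll)
    }
    t_dl0 <- now_ts()
    payloads <- lapply(site_ids, function(s) {
      pth <- want[[s]]
      if (!is.null(log_env))
        log_env$records[[length(log_env$records) + 1L]] <-
          log_record(s, "partner", directive$iteration, "transfer",
                     as.numeric(file.mtime(pth)), t_dl0)
      center_read_payload(pth, s, seq)
    })
    t_dl1 <- now_ts()
    if (!is.null(log_env))
      log_env$records[[length(log_env$records) + 1L]] <-
        log_record("center", "center", directive$iteration, "download",
                   t_dl0, t_dl1)
    seq_counter$last_collect_end <- t_dl1
    payloads
  }
}

#' Run the analysis-center node of the file-exchange protocol
#'
#' Drives a full distributed fit over partner processes that are already
#' running (or will start) against the same `workdir`: distributes
#' directives, waits for payload triggers, aggregates, iterates to
#' convergence, issues the diagnostics round, and finally a stop
#' directive.
#'
#' @param workdir Shared protocol directory.
#' @param site_ids Character vector of partner identifiers.
#' @param spec The shared [dra_spec()].
#' @param poll Poll interval in seconds.
#' @param timeout Seconds to wait for any single collection round.
#' @return A `"dra_fit"` object (with `transfer_log` attached).
#' @export
dra_run_center <- function(workdir, site_ids, spec, poll = 0.05,
                           timeout = 120) {
  protocol_dirs(workdir, site_ids)
  log_env <- new.env(parent = emptyenv())
  log_env$records <- list()
  collect <- center_collect_factory(workdir, site_ids, spec,
                                    step_fns = NULL, poll = poll,
                                    timeout = timeout, log_env = log_env)
  res <- run_center_algorithm(spec, collect)
  collect(new_directive("stop", -1L, spec))
  finish_fit_from_center(res, spec, workdir, site_ids, log_env)
}

finish_fit_from_center <- function(res, spec, workdir, site_ids, log_env) {
  # give partners a moment to write their logs/acks
  for (i in 1:100) {
    acks <- list.files(workdir, pattern = "^ack_", recursive = TRUE)
    if (length(acks) >= length(site_ids)) break
    Sys.sleep(0.02)
  }
  partner_logs <- lapply(site_ids, function(s) {
    p <- file.path(dir_from(workdir, s), sprintf("log_%s.jsonl", s))
    if (file.exists(p)) read_log_file(p) else NULL
  })
  log <- do.call(rbind, c(log_env$records, partner_logs))
  cn <- design_colnames(spec)
  beta <- stats::setNames(res$beta, cn)
  se <- stats::setNames(res$se, cn)
  vcov <- res$vcov
  dimnames(vcov) <- list(cn, cn)
  structure(
    list(coefficients = beta, se = se, vcov = vcov,
         fit_statistics = res$fit_statistics,
         iterations = res$iterations, converged = res$converged,
         n = res$n, site_ids = site_ids, site_sizes = NULL,
         diagnostics = res$diagnostics, spec = spec, engine = "files",
         transfer_log = log, call = sys.call(-1L)),
    class = "dra_fit")
}

# Cooperative single-process run: the center algorithm advances every
# partner's state machine inside its own wait loop, so the whole protocol
# (all file exchanges included) executes deterministically in one process.
run_protocol_cooperative <- function(envs, spec, workdir = NULL,
                                     keep_workdir = FALSE) {
  if (is.null(workdir))
    workdir <- tempfile("dranet_run_")
  site_ids <- vapply(envs, `[[`, "", "site_id")
  protocol_dirs(workdir, site_ids)
  if (!keep_workdir) on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
  states <- lapply(envs, function(e)
    partner_state(workdir, e$site_id, e, spec))
  step_fns <- lapply(states, function(st) function() partner_step(st))
  log_env <- new.env(parent = emptyenv())
  log_env$records <- list()
  collect <- center_collect_factory(workdir, site_ids, spec,
                                    step_fns = step_fns, timeout = 120,
                                    log_env = log_env)
  res <- run_center_algorithm(spec, collect)
  collect(new_directive("stop", -1L, spec))
  for (f in step_fns) f()              # let partners process the stop
  partner_logs <- lapply(site_ids, function(s) {
    p <- file.path(dir_from(workdir, s), sprintf("log_%s.jsonl", s))
    if (file.exists(p)) read_log_file(p) else NULL
  })
  log <- do.call(rbind, c(log_env$records, partner_logs))
  list(result = res, transfer_log = log, workdir = workdir)
}

# ---------------------------------------------------------------------

#' Summarize per-step protocol timings
#'
#' Reduces a transfer log to mean and standard error of the duration of
#' each protocol step (download, compute, upload, transfer) per node
#' class, plus the average wall time per protocol round and the total run
#' time — the operational-performance summary of a distributed run.
#'
#' @param log A transfer log (`data.frame` with columns `node`,
#'   `node_class`, `iteration`, `step`, `start`, `end`), as attached to a
#'   file-engine [dra_fit()] result.
#' @return Object of class `"dra_timing_summary"`: a data frame with one
#'   row per (node class, step) observed — absent step categories are
#'   simply absent — plus attributes `avg_round_time` and `total_time`.
#' @export
summarize_timings <- function(log) {
  stopifnot(is.data.frame(log), nrow(log) >= 1L)
  log <- log[log$step %in% c("download", "compute", "upload", "transfer"), ]
  dur <- log$end - log$start
  key <- interaction(log$node_class, log$step, drop = TRUE)
  mean_ <- tapply(dur, key, mean)
  se_ <- tapply(dur, key, function(x)
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0)
  n_ <- tapply(dur, key, length)
  parts <- strsplit(names(mean_), ".", fixed = TRUE)
  out <- data.frame(
    node_class = vapply(parts, `[`, "", 1L),
    step = vapply(parts, `[`, "", 2L),
    n = as.integer(n_), mean = as.numeric(mean_), se = as.numeric(se_),
    stringsAsFactors = FALSE)
  out <- out[order(out$node_class, out$step), ]
  rownames(out) <- NULL
  rounds <- tapply(log$end, log$iteration, max) -
    tapply(log$start, log$iteration, min)
  structure(out, class = c("dra_timing_summary", "data.frame"),
            avg_round_time = mean(rounds),
            total_time = max(log$end) - min(log$start))
}

#' @export
print.dra_timing_summary <- function(x, ...) {
  cat("Protocol step timings (seconds)\n")
  df <- as.data.frame(x)
  df$mean <- sprintf("%.4f", df$mean)
  df$se <- sprintf("%.4f", df$se)
  print(df, row.names = FALSE)
  cat(sprintf("Average round time: %.4f s; total run time: %.4f s\n",
              attr(x, "avg_round_time"), attr(x, "total_time")))
  invisible(x)
}

# ---------------------------------------------------------------------

#' Audit a protocol directory for individual-level data
#'
#' Walks every file present in the transfer directories of a protocol run
#' and verifies that each one is a well-formed instance of an allowed
#' schema: directive, payload, trigger, acknowledgement, error report, or
#' timing log — and that payloads carry only whitelisted summary-level
#' components. Any other file, or any payload with undeclared components,
#' is reported as a violation.
#'
#' @param workdir Protocol directory of a (kept) file-engine run.
#' @return Data frame with columns `file`, `type`, `ok`, `detail`;
#'   attribute `clean` is `TRUE` when no violations were found.
#' @export
dra_audit_workdir <- function(workdir) {
  boxes <- list.files(workdir, pattern = "^(to|from)_", full.names = FALSE)
  files <- unlist(lapply(boxes, function(b)
    file.path(b, list.files(file.path(workdir, b), recursive = TRUE))),
    use.names = FALSE)
  if (!length(files))
    return(structure(data.frame(file = character(0), type = character(0),
                                ok = logical(0), detail = character(0)),
                     clean = TRUE))
  rows <- lapply(files, function(f) {
    path <- file.path(workdir, f)
    base <- basename(f)
    check <- function(type, expr) {
      ok <- tryCatch({ expr; TRUE }, error = function(e) FALSE)
      data.frame(file = f, type = type, ok = ok,
                 detail = if (ok) "" else "failed schema validation",
                 stringsAsFactors = FALSE)
    }
    if (grepl("\\.trigger$", base)) {
      data.frame(file = f, type = "trigger",
                 ok = file.size(path) == 0,
                 detail = if (file.size(path) == 0) "" else "non-empty trigger",
                 stringsAsFactors = FALSE)
    } else if (grepl("^directive_\\d+\\.json$", base)) {
      check("directive", read_directive(path))
    } else if (grepl("^payload_\\d+_.+\\.dra$", base)) {
      check("payload", read_payload(path))
    } else if (grepl("^(ack|error)_\\d+_.+\\.json$", base)) {
      check("ack/error", jsonlite::fromJSON(readLines(path, warn = FALSE)))
    } else if (grepl("^log_.+\\.jsonl$", base)) {
      check("log", read_log_file(path))
    } else {
      data.frame(file = f, type = "unknown", ok = FALSE,
                 detail = "file outside the protocol schema",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  structure(out, clean = all(out$ok))
}
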
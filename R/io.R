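#' Write a trajectory as CSV with metadata header
#'
#' Emits `#`-prefixed metadata lines (parameters, seed, topology summary,
#' detected crash time) followed by a header row and one row per step.
#' Missing values are written as empty fields.
#'
#' @param trajectory A `decay_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "decay_trajectory"))
  pars <- attr(trajectory, "params")
  th <- pars$threshold
  meta <- c(
    sprintf("# decaynet trajectory"),
    sprintf("# n0=%d e0=%d", attr(trajectory, "n0"), attr(trajectory, "e0")),
    sprintf("# p=%g q=%g r=%g tau=%d p_link=%g p_spawn=%g", pars$p, pars$q,
            pars$r, pars$tau, pars$p_link, pars$p_spawn),
    if (th$type == "constant") sprintf("# threshold=constant value=%g", th$value)
    else sprintf("# threshold=gaussian mu=%g sigma=%g", th$mean, th$sd),
    sprintf("# seed=%s", if (is.null(pars$seed)) "NULL" else pars$seed),
    sprintf("# t_c=%s stopped=%s",
            if (is.na(attr(trajectory, "t_c"))) "NA" else attr(trajectory, "t_c"),
            attr(trajectory, "stopped"))
  )
  con <- tryCatch(file(path, "w"),
                  error = function(e) io_error("cannot write: ", path))
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(as.data.frame(trajectory), con, sep = ",", na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Reads a file written by [write_trajectory()] (or any CSV with a `t` and
#' `f_a` column; `#` metadata lines are skipped). The reconstructed object
#' carries a `t_c` recomputed from its `mean_excess` column when present.
#'
#' @param path Path to the CSV file.
#' @return A `decay_trajectory` (without the originating `params`).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) io_error("cannot read trajectory: ", path)
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("t", "f_a") %in% names(d)))
    io_error("not a trajectory file (need columns t, f_a): ", path)
  cls <- c("decay_trajectory", "data.frame")
  tc <- if ("mean_excess" %in% names(d)) {
    neg <- which(d$mean_excess < 0)
    if (length(neg)) d$t[neg[1L]] else NA_real_
  } else NA_real_
  structure(d, t_c = tc, crash_times = if (is.na(tc)) integer(0) else tc,
            stopped = "unknown", n0 = NA_integer_, e0 = NA_integer_,
            params = NULL, class = cls)
}
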
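# File formats: trajectory CSV, temperature CSV, multi-page TIFF stacks.

#' Read trajectories from CSV
#'
#' Expects columns `fly_id`, `t_s`, `x_mm`, `y_mm` and optionally
#' `condition` and `stimulus_onset_s`.  Rows are sorted by
#' (`fly_id`, `t_s`); each fly must lie on a uniform time grid.
#'
#' @param path CSV file path.
#' @return Trajectory data frame with the `sample_dt_s` and (when a
#'   stimulus onset column is present) `stimulus` attributes set.
#' @export
read_trajectories_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("fly_id", "t_s", "x_mm", "y_mm")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  d <- d[order(d$fly_id, d$t_s), , drop = FALSE]
  rownames(d) <- NULL
  dts <- unlist(lapply(split(d$t_s, d$fly_id), diff), use.names = FALSE)
  if (length(dts) == 0) stop("each fly needs at least 2 samples", call. = FALSE)
  dt <- stats::median(dts)
  for (id in unique(d$fly_id)) {
    t <- d$t_s[d$fly_id == id]
    gaps <- which(abs(diff(t) - dt) > 1e-6 * max(1, dt))
    if (length(gaps) > 0)
      stop(sprintf("non-uniform time grid for fly '%s' at row %d (t = %g s)",
                   id, gaps[1] + 1, t[gaps[1] + 1]), call. = FALSE)
  }
  attr(d, "sample_dt_s") <- dt
  if ("stimulus_onset_s" %in% names(d)) {
    onset <- unique(d$stimulus_onset_s)
    if (length(onset) == 1 && is.finite(onset))
      attr(d, "stimulus") <- stimulus_event(onset_s = onset)
  }
  d
}

#' Write trajectories to CSV
#'
#' @param traj Trajectory data frame (as from
#'   [generate_locomotor_session()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(traj, path) {
  out <- traj
  stim <- attr(traj, "stimulus")
  if (!is.null(stim)) out$stimulus_onset_s <- stim$onset_s
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write multi-page grayscale TIFF stacks
#'
#' Stacks are stored one channel per file as 32-bit float multi-page
#' grayscale TIFF.
#'
#' @param stack Numeric array `height x width x pages`.
#' @param path TIFF file path.
#' @return `write_stack_tiff()` returns `path` invisibly;
#'   `read_stack_tiff()` returns the array.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                               length(pages)))
}

#' Read and write a temperature trace CSV
#'
#' Columns `t_s`, `temp_c`.
#'
#' @param ramp Data frame with `t_s`, `temp_c`.
#' @param path CSV path.
#' @return The trace data frame (read) or `path` invisibly (write).
#' @export
write_temperature_csv <- function(ramp, path) {
  utils::write.csv(ramp[, c("t_s", "temp_c")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_temperature_csv
#' @export
read_temperature_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "temp_c") %in% names(d)))
    stop("temperature CSV needs columns t_s, temp_c", call. = FALSE)
  d
}
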
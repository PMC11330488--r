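#' Read a plate-reader kinetic table
#'
#' Reads a delimited table whose first column is time (header `time_h` or
#' `time_s`, seconds converted to hours automatically) and remaining
#' columns are one well each, and pairs it with a well-to-condition map.
#'
#' @param path Path to a tab- or comma-delimited file.
#' @param conditions Data frame with columns `well`, `m_total_uM`,
#'   `seed_pct` and `direction` mapping well column names to assay
#'   conditions.
#' @param sep Field separator; `NULL` (default) tries tab then comma.
#' @return List of [kinetic_trace()] objects, one per mapped well.
#' @export
read_plate_table <- function(path, conditions, sep = NULL) {
  tab <- read_delim_auto(path, sep)
  time_col <- names(tab)[1]
  times <- tab[[1]]
  if (identical(tolower(time_col), "time_s")) times <- times / 3600
  req <- c("well", "m_total_uM", "seed_pct", "direction")
  if (!all(req %in% names(conditions))) {
    stop("conditions needs columns: ", paste(req, collapse = ", "))
  }
  missing <- setdiff(conditions$well, names(tab))
  if (length(missing) > 0) {
    stop("wells absent from the table: ", paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(conditions)), function(i) {
    kinetic_trace(
      times, tab[[conditions$well[i]]],
      m_total = conditions$m_total_uM[i],
      seed_mass = conditions$seed_pct[i] / 100 * conditions$m_total_uM[i],
      direction = as.character(conditions$direction[i]))
  })
}

#' Write a fibril trajectory as a delimited table
#'
#' @param traj A `fibril_trajectory`.
#' @param path Output path; tab-separated with columns `time_h`, `m_uM`,
#'   `M_uM`, `P_uM`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fibril_trajectory"))
  utils::write.table(
    data.frame(time_h = traj$times, m_uM = traj$m, M_uM = traj$M,
               P_uM = traj$P),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fibril length measurements
#'
#' Accepts either one row per fibril (columns `t_h`, `length`) or
#' per-timepoint summaries (columns `t_h`, `mean_length`, `n`).
#'
#' @param path Path to a delimited file.
#' @param sep Field separator; `NULL` tries tab then comma.
#' @return List of [length_sample()] objects ordered by time.
#' @export
read_length_table <- function(path, sep = NULL) {
  tab <- read_delim_auto(path, sep)
  if (all(c("t_h", "length") %in% names(tab))) {
    lapply(sort(unique(tab$t_h)), function(t) {
      length_sample(t, lengths = tab$length[tab$t_h == t])
    })
  } else if (all(c("t_h", "mean_length", "n") %in% names(tab))) {
    lapply(seq_len(nrow(tab)), function(i) {
      length_sample(tab$t_h[i], mean_length = tab$mean_length[i],
                    n = tab$n[i])
    })
  } else {
    stop("expected columns t_h + length, or t_h + mean_length + n")
  }
}

#' Read oligomer time series per condition
#'
#' @param path Delimited file with columns `time_h`, `S_rel`, and
#'   optionally `sem`, `n_rep`, `condition`.
#' @param sep Field separator; `NULL` tries tab then comma.
#' @return Named list of [oligomer_series()], one per condition.
#' @export
read_oligomer_table <- function(path, sep = NULL) {
  tab <- read_delim_auto(path, sep)
  if (!all(c("time_h", "S_rel") %in% names(tab))) {
    stop("expected columns time_h and S_rel")
  }
  if (!"condition" %in% names(tab)) tab$condition <- "all"
  out <- lapply(split(tab, tab$condition), function(d) {
    d <- d[order(d$time_h), ]
    oligomer_series(
      d$time_h, d$S_rel,
      sem = if ("sem" %in% names(d)) d$sem else NA_real_,
      n_rep = if ("n_rep" %in% names(d)) d$n_rep else 1L)
  })
  out
}

#' Read a photon-count timetrace
#'
#' @param path Delimited file with columns `bin_index` and `counts`.
#' @param bin_width_ms Bin width in milliseconds.
#' @param position Optional position identifier.
#' @param sep Field separator; `NULL` tries tab then comma.
#' @return A [photon_trace()].
#' @export
read_photon_table <- function(path, bin_width_ms = 1, position = NA,
                              sep = NULL) {
  tab <- read_delim_auto(path, sep)
  if (!all(c("bin_index", "counts") %in% names(tab))) {
    stop("expected columns bin_index and counts")
  }
  photon_trace(tab$counts[order(tab$bin_index)],
               bin_width_ms = bin_width_ms, position = position)
}

read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
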
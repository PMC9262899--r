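#' Read an OpenSim-style storage table (.sto/.mot)
#'
#' Parses the text "storage" dialect used by motion-analysis tooling: a free
#' header terminated by an \code{endheader} line, optionally carrying
#' \code{nRows=}/\code{nColumns=} fields, followed by a tab- or
#' whitespace-delimited table whose first row names the columns (first column
#' conventionally \code{time}).
#'
#' @param path File path.
#' @return Data frame with the table; header lines in attribute
#'   \code{"header"}.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- match(TRUE, trimws(tolower(lines)) == "endheader")
  if (is.na(end)) stop("not a storage file: no 'endheader' line in ", path)
  header <- lines[seq_len(end - 1)]
  cols <- strsplit(trimws(lines[end + 1]), "[\t ]+")[[1]]
  body <- lines[-seq_len(end + 1)]
  body <- body[nzchar(trimws(body))]
  dat <- do.call(rbind, lapply(strsplit(trimws(body), "[\t ]+"),
                               as.numeric))
  dat <- as.data.frame(dat)
  names(dat) <- cols
  nr <- sub(".*nRows=([0-9]+).*", "\\1",
            grep("nRows=", header, value = TRUE)[1])
  if (!is.na(nr) && length(nr) && grepl("^[0-9]+$", nr) &&
      as.integer(nr) != nrow(dat))
    warning("nRows in header (", nr, ") does not match table (",
            nrow(dat), ")")
  attr(dat, "header") <- header
  dat
}

#' Write a gait trial to CSV
#'
#' Columns: time, the three joint angles (rad), the three joint moments
#' (N m), stance flag, intersegmental knee axial force (N), vertical GRF (N).
#' Bodyweight is carried in a comment line.
#'
#' @param trial A \code{gait_trial}.
#' @param path Output path.
#' @export
write_gait_trial <- function(trial, path) {
  df <- data.frame(time = trial$t,
                   hip_angle = trial$q[, "hip_flexion"],
                   knee_angle = trial$q[, "knee_flexion"],
                   ankle_angle = trial$q[, "ankle_plantarflexion"],
                   hip_moment = trial$M_ID[, "hip_flexion"],
                   knee_moment = trial$M_ID[, "knee_flexion"],
                   ankle_moment = trial$M_ID[, "ankle_plantarflexion"],
                   stance = as.integer(trial$stance_mask),
                   interseg_axial = trial$interseg_axial,
                   grf_vertical = trial$grf_vertical)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gait_trial bodyweight_N=%.6f", trial$bodyweight), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a gait trial written by \code{\link{write_gait_trial}}
#'
#' @param path CSV path.
#' @return A \code{gait_trial}.
#' @export
read_gait_trial <- function(path) {
  first <- readLines(path, n = 1)
  bw <- as.numeric(sub(".*bodyweight_N=([0-9.eE+-]+).*", "\\1", first))
  if (!is.finite(bw)) stop("missing bodyweight header in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  dofs <- c("hip_flexion", "knee_flexion", "ankle_plantarflexion")
  q <- as.matrix(df[, c("hip_angle", "knee_angle", "ankle_angle")])
  M <- as.matrix(df[, c("hip_moment", "knee_moment", "ankle_moment")])
  colnames(q) <- colnames(M) <- dofs
  structure(list(t = df$time, q = q, M_ID = M,
                 stance_mask = df$stance > 0,
                 interseg_axial = df$interseg_axial,
                 grf_vertical = df$grf_vertical, bodyweight = bw),
            class = "gait_trial")
}

#' Write muscle parameters to CSV
#'
#' Columns: name, f_o_m [N], l_o_m [m], l_s_t [m], alpha_o [rad].
#'
#' @param model A \code{planar_model}.
#' @param path Output path.
#' @export
write_muscle_params <- function(model, path) {
  rows <- do.call(rbind, lapply(model$muscles, function(m)
    data.frame(name = m$params$name, f_o_m = m$params$f_o_m,
               l_o_m = m$params$l_o_m, l_s_t = m$params$l_s_t,
               alpha_o = m$params$alpha_o)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a muscle parameter table from CSV
#'
#' @param path CSV with columns name, f_o_m, l_o_m, l_s_t, alpha_o.
#' @return Named list of \code{muscle_params}.
#' @export
read_muscle_params <- function(path) {
  df <- utils::read.csv(path)
  need <- c("name", "f_o_m", "l_o_m", "l_s_t", "alpha_o")
  if (!all(need %in% names(df)))
    stop("muscle parameter CSV must have columns: ",
         paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    muscle_params(df$name[i], df$f_o_m[i], df$l_o_m[i], df$l_s_t[i],
                  df$alpha_o[i]))
  names(out) <- df$name
  out
}

#' Write an EMG recording or envelope series to CSV
#'
#' First column \code{time} (s); one column per channel; a comment line
#' records the sampling rate.
#'
#' @param x An \code{emg_recording} or \code{envelope_series}.
#' @param path Output path.
#' @export
write_emg_csv <- function(x, path) {
  stopifnot(inherits(x, "emg_recording") || inherits(x, "envelope_series"))
  t <- seq(0, by = 1 / x$fs, length.out = nrow(x$channels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.6f", x$fs), con)
  utils::write.csv(data.frame(time = t, x$channels), con, row.names = FALSE)
  invisible(path)
}
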
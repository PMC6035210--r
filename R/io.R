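# CSV exchange of deformation and stress histories. Comma-separated,
# '.' decimal, mandatory header, SI units: columns t (s) and F11..F33
# (dimensionless) or s11..s33 (Pa), row-major tensor components.

F_COLS <- as.vector(t(outer(1:3, 1:3, function(i, j) paste0("F", i, j))))
S_COLS <- as.vector(t(outer(1:3, 1:3, function(i, j) paste0("s", i, j))))

#' Write / read a deformation history as CSV
#'
#' Columns `t`, `F11`, `F12`, ..., `F33` (row-major). The reader validates
#' the schema and the history invariants; writers and readers round-trip
#' losslessly.
#'
#' @param history a [deformation_history()].
#' @param path CSV file path.
#' @return the path (writer) or a [deformation_history()] (reader).
#' @export
write_deformation_history <- function(history, path) {
  stopifnot(inherits(history, "deformation_history"))
  n <- length(history$t)
  M <- t(vapply(seq_len(n), function(i) as.vector(t(history$F[, , i])),
                numeric(9)))
  df <- data.frame(t = history$t, M)
  names(df) <- c("t", F_COLS)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deformation_history
#' @export
read_deformation_history <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  miss <- setdiff(c("t", F_COLS), names(df))
  if (length(miss))
    stop("malformed history CSV (", path, "), missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(df)
  Fs <- array(0, c(3, 3, n))
  for (i in seq_len(n))
    Fs[, , i] <- matrix(as.numeric(df[i, F_COLS]), 3, 3, byrow = TRUE)
  deformation_history(df$t, Fs)
}

#' Write / read a stress history as CSV
#'
#' Columns `t`, `s11`, ..., `s33` (row-major Cauchy stress, Pa).
#'
#' @param stress_hist a [stress_history()].
#' @param path CSV file path.
#' @return the path (writer) or a [stress_history()] (reader).
#' @export
write_stress_history <- function(stress_hist, path) {
  stopifnot(inherits(stress_hist, "stress_history"))
  n <- length(stress_hist$t)
  M <- t(vapply(seq_len(n), function(i) as.vector(t(stress_hist$sigma[, , i])),
                numeric(9)))
  df <- data.frame(t = stress_hist$t, M)
  names(df) <- c("t", S_COLS)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stress_history
#' @export
read_stress_history <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  miss <- setdiff(c("t", S_COLS), names(df))
  if (length(miss))
    stop("malformed stress CSV (", path, "), missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(df)
  S <- array(0, c(3, 3, n))
  for (i in seq_len(n))
    S[, , i] <- matrix(as.numeric(df[i, S_COLS]), 3, 3, byrow = TRUE)
  stress_history(df$t, S)
}
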
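#' Construct a SAXS curve
#'
#' A `saxs_curve` holds one small-angle scattering profile: momentum transfer
#' `q` (inverse angstrom), intensity `I` (arbitrary units), optional intensity
#' uncertainty `sigmaI`, and optional time-after-mixing metadata for
#' time-resolved experiments.
#'
#' @param q Momentum transfer, inverse angstrom; strictly increasing, positive.
#' @param I Intensity, arbitrary units; finite.
#' @param sigmaI Optional intensity uncertainty, same units as `I`;
#'   non-negative.
#' @param t_after_mix Optional time after mixing, seconds.
#' @param label Free-text label.
#' @return An object of class `saxs_curve` (a data frame with columns `q`,
#'   `I`, and `sigmaI` when present, plus metadata attributes).
#' @export
saxs_curve <- function(q, I, sigmaI = NULL, t_after_mix = NA_real_,
                       label = "") {
  q <- as.numeric(q)
  I <- as.numeric(I)
  if (length(q) != length(I)) {
    stop_invalid_parameter("q and I must have the same length")
  }
  if (length(q) < 8L) {
    stop_invalid_parameter("a SAXS curve needs at least 8 points")
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop_invalid_parameter("q must be finite and positive")
  }
  if (any(diff(q) <= 0)) {
    stop_invalid_parameter("q must be strictly increasing")
  }
  if (any(!is.finite(I))) {
    stop_invalid_parameter("I must be finite")
  }
  df <- data.frame(q = q, I = I)
  if (!is.null(sigmaI)) {
    sigmaI <- as.numeric(sigmaI)
    if (length(sigmaI) != length(q)) {
      stop_invalid_parameter("sigmaI must match the length of q")
    }
    if (any(!is.finite(sigmaI)) || any(sigmaI < 0)) {
      stop_invalid_parameter("sigmaI must be finite and non-negative")
    }
    df$sigmaI <- sigmaI
  }
  structure(df,
            t_after_mix = as.numeric(t_after_mix),
            label = as.character(label),
            class = c("saxs_curve", "data.frame"))
}

#' @export
print.saxs_curve <- function(x, ...) {
  lab <- attr(x, "label")
  tm <- attr(x, "t_after_mix")
  cat("SAXS curve", if (nzchar(lab)) paste0("'", lab, "'"), "\n")
  cat(sprintf("  %d points, q in [%s, %s] 1/Angstrom\n", nrow(x),
              fmt_num(min(x$q)), fmt_num(max(x$q))))
  if (!is.na(tm)) cat(sprintf("  t after mixing: %s s\n", fmt_num(tm)))
  cat(sprintf("  sigmaI: %s\n", if ("sigmaI" %in% names(x)) "present" else "absent"))
  invisible(x)
}

#' Read a plain-text SAXS curve
#'
#' Reads the whitespace-separated `.dat` dialect: two or three numeric
#' columns (`q`, `I`, optional `sigmaI`), with `#`-prefixed header lines
#' ignored. If a header line declares q in inverse nanometres (contains
#' `1/nm` or `nm^-1`), q is converted to inverse angstrom.
#'
#' @param path Path to the file.
#' @param t_after_mix Optional time-after-mixing metadata, seconds.
#' @param label Label; defaults to the file name.
#' @return A [saxs_curve].
#' @export
read_saxs_dat <- function(path, t_after_mix = NA_real_, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop_insufficient_data("no data rows in SAXS file")
  con <- textConnection(body)
  on.exit(close(con), add = TRUE)
  tab <- read.table(con, header = FALSE)
  if (ncol(tab) < 2) stop_invalid_parameter("SAXS file must have >= 2 columns")
  q <- tab[[1]]
  nm_units <- any(grepl("1/nm|nm\\^-1|nm-1", header, ignore.case = TRUE))
  if (nm_units) q <- q / 10
  tm_line <- grep("t_after_mix_s:", header, value = TRUE)
  if (is.na(t_after_mix) && length(tm_line)) {
    t_after_mix <- as.numeric(sub(".*t_after_mix_s:\\s*", "", tm_line[1]))
  }
  saxs_curve(q, tab[[2]],
             sigmaI = if (ncol(tab) >= 3) tab[[3]] else NULL,
             t_after_mix = t_after_mix, label = label)
}

#' Write a SAXS curve to the plain-text format
#'
#' @param curve A [saxs_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  hdr <- c("# phasekin SAXS curve (q in 1/Angstrom)",
           sprintf("# label: %s", attr(curve, "label")))
  tm <- attr(curve, "t_after_mix")
  if (!is.na(tm)) hdr <- c(hdr, sprintf("# t_after_mix_s: %.9g", tm))
  writeLines(hdr, path)
  suppressWarnings(write.table(as.data.frame(curve), path, append = TRUE,
                               row.names = FALSE, col.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' Logarithmic q-binning of a SAXS curve for display
#'
#' Bins a curve into geometrically spaced q bins (geometric-mean q per bin,
#' arithmetic mean intensity). Intended for plotting only; fits always use
#' the raw curve.
#'
#' @param curve A [saxs_curve].
#' @param n_bins Number of bins (default 30).
#' @return A data frame with columns `q`, `I`, `n`.
#' @export
log_bin_curve <- function(curve, n_bins = 30) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (n_bins < 2) stop_invalid_parameter("n_bins must be >= 2")
  edges <- exp(seq(log(min(curve$q)), log(max(curve$q)), length.out = n_bins + 1))
  idx <- findInterval(curve$q, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  qb <- tapply(curve$q, idx, function(z) exp(mean(log(z))))
  Ib <- tapply(curve$I, idx, mean)
  nb <- tapply(curve$q, idx, length)
  data.frame(q = as.numeric(qb), I = as.numeric(Ib), n = as.integer(nb),
             row.names = NULL)
}
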
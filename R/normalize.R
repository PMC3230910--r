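#' Midpoint of the shorth
#'
#' The shorth of a sample is the shortest interval containing half of the
#' data; its midpoint is a robust estimator of the mode, less affected by
#' skewness and outliers than the mean or median, and is used here as the
#' per-plate correction coefficient.
#'
#' The window length is `h = ceiling(n/2)`. All contiguous windows of `h`
#' sorted values are scanned; among windows of minimal range, the interval
#' midpoints `(min + max)/2` are averaged (this preserves the symmetry of
#' symmetric samples). `method = "mean"` instead averages the mean of the
#' values inside each minimal window.
#'
#' @param x numeric vector; non-finite values are excluded with a warning.
#' @param method `"interval"` (default, interval midpoint) or `"mean"`.
#' @return The shorth midpoint, a single number.
#' @export
shorth_midpoint <- function(x, method = c("interval", "mean")) {
  method <- match.arg(method)
  bad <- !is.finite(x)
  if (any(bad)) {
    warning(sum(bad), " non-finite value(s) excluded from shorth")
    x <- x[!bad]
  }
  n <- length(x)
  if (n == 0L) stop("value error: shorth of an empty sample")
  if (n == 1L) return(x)
  xs <- sort(x)
  h <- ceiling(n / 2)
  i <- seq_len(n - h + 1L)
  rng <- xs[i + h - 1L] - xs[i]
  tol <- sqrt(.Machine$double.eps) * max(1, abs(diff(range(xs))))
  best <- which(rng <= min(rng) + tol)
  if (method == "interval") {
    mean((xs[best] + xs[best + h - 1L]) / 2)
  } else {
    mean(vapply(best, function(b) mean(xs[b:(b + h - 1L)]), numeric(1)))
  }
}

#' Adjust a screen for plate effects
#'
#' Log2-transforms the raw readouts and subtracts, per plate, a correction
#' coefficient `mu_p` estimated as the midpoint of the shorth of that plate's
#' co-RNAi (non-control) log2 values. Control wells are transformed and
#' centered with the same `mu_p` but never contribute to it. After
#' normalization the per-plate shorth midpoint of non-control values is 0.
#'
#' @param screen a `screen_table` with positive readouts.
#' @param method passed to [shorth_midpoint()].
#' @return A `normalized_screen`: the input screen with a `value` column
#'   (log2, plate-centered) and a `centers` element (named per-plate `mu_p`).
#' @export
normalize_plates <- function(screen, method = "interval") {
  w <- screen$wells
  if (any(is.na(w$readout)))
    stop("value error: missing readouts; normalize a measured screen")
  ctrl <- well_is_control(screen)
  lg <- log2(w$readout)
  plates <- unique(w$plate)
  centers <- vapply(plates, function(p) {
    sel <- w$plate == p & !ctrl
    if (!any(sel))
      stop("normalization error: plate '", p, "' has only control wells")
    shorth_midpoint(lg[sel], method = method)
  }, numeric(1))
  screen$wells$value <- lg - centers[w$plate]
  screen$centers <- centers
  class(screen) <- unique(c("normalized_screen", class(screen)))
  screen
}

#' Z'-factor of control separation
#'
#' `1 - 3 (sd+ + sd-) / |mean+ - mean-|`, with sample (n-1) standard
#' deviations. Values near 1 indicate excellent separation of the positive
#' and negative controls; values below 0.5 flag a problematic assay window.
#'
#' @param positives,negatives numeric vectors of control values (same scale).
#' @return The Z'-factor.
#' @export
z_prime_factor <- function(positives, negatives) {
  if (length(positives) < 2 || length(negatives) < 2)
    stop("value error: need at least 2 values per control group")
  mu_p <- mean(positives); mu_n <- mean(negatives)
  if (mu_p == mu_n) stop("undefined error: control group means are equal")
  1 - 3 * (stats::sd(positives) + stats::sd(negatives)) / abs(mu_p - mu_n)
}

#' Screen quality-control report
#'
#' Computes, from a normalized screen: per-plate spatial matrices of the
#' normalized values (with a parallel control mask), all pairwise replicate
#' Pearson correlations on pair-matched values, per-plate and screen-wide
#' Z'-factors (where both control classes exist; `NA` otherwise), and
#' per-plate distribution summaries of the non-control values.
#'
#' @param screen a `normalized_screen`.
#' @return A list of class `qc_report` with elements `spatial`,
#'   `replicate_cor`, `zprime`, `plate_summary`.
#' @export
qc_report <- function(screen) {
  stopifnot(inherits(screen, "normalized_screen"))
  w <- screen$wells
  ctrl <- well_is_control(screen)
  role <- stats::setNames(screen$reagents$control_role, screen$reagents$id)
  wclass <- ifelse(role[w$reagent_row] != "none", role[w$reagent_row],
                   ifelse(role[w$reagent_col] != "none",
                          role[w$reagent_col], "none"))
  plates <- unique(w$plate)

  spatial <- lapply(plates, function(p) {
    sub <- w[w$plate == p, ]
    m <- matrix(NA_real_, screen$plate_rows, screen$plate_cols,
                dimnames = list(row_label(seq_len(screen$plate_rows)),
                                seq_len(screen$plate_cols)))
    cm <- matrix(FALSE, screen$plate_rows, screen$plate_cols)
    m[cbind(sub$row, sub$col)] <- sub$value
    cm[cbind(sub$row, sub$col)] <- ctrl[w$plate == p]
    list(values = m, control = cm)
  })
  names(spatial) <- plates

  ## pair-matched replicate correlation: one column per (biorep, techrep)
  sample_sel <- !ctrl & !well_is_self_pair(screen)
  s <- w[sample_sel, ]
  rep_lab <- paste(s$bio_rep, s$tech_rep, sep = ".")
  keys <- pair_key(s$reagent_row, s$reagent_col)
  wide <- tapply(s$value, list(keys, rep_lab), mean)
  rc <- NULL
  if (ncol(wide) >= 2) {
    cm <- stats::cor(wide, use = "pairwise.complete.obs")
    ij <- which(upper.tri(cm), arr.ind = TRUE)
    rc <- data.frame(rep1 = rownames(cm)[ij[, 1]],
                     rep2 = colnames(cm)[ij[, 2]],
                     r = cm[ij], stringsAsFactors = FALSE)
  }

  zp_for <- function(sel) {
    pos <- w$value[sel & wclass == "positive"]
    neg <- w$value[sel & wclass == "negative"]
    if (length(pos) >= 2 && length(neg) >= 2 && mean(pos) != mean(neg))
      z_prime_factor(pos, neg) else NA_real_
  }
  zprime <- data.frame(plate = c(plates, "screen"),
                       z_prime = c(vapply(plates, function(p)
                         zp_for(w$plate == p), numeric(1)),
                         zp_for(rep(TRUE, nrow(w)))),
                       stringsAsFactors = FALSE)

  plate_summary <- do.call(rbind, lapply(plates, function(p) {
    v <- w$value[w$plate == p & !ctrl]
    data.frame(plate = p, n = length(v), min = min(v),
               q25 = unname(stats::quantile(v, .25)), median = stats::median(v),
               q75 = unname(stats::quantile(v, .75)), max = max(v),
               stringsAsFactors = FALSE)
  }))

  structure(list(spatial = spatial, replicate_cor = rc, zprime = zprime,
                 plate_summary = plate_summary),
            class = "qc_report")
}

#' Write a QC report to a directory of plain-text tables
#'
#' @param qc a [qc_report()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(qc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(qc$spatial))
    utils::write.table(qc$spatial[[p]]$values,
                       file.path(dir, paste0("spatial_", p, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(qc$replicate_cor))
    utils::write.table(qc$replicate_cor,
                       file.path(dir, "replicate_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc$zprime, file.path(dir, "zprime.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc$plate_summary, file.path(dir, "plate_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
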
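## Extracellular metabolomics: blank correction, per-cell exchange rates
## with uncertainty, and log2 fold-change summaries.
##
## Concentration tables are long-format data.frames with the columns
## metabolite, time_h, conc_mM, conc_sd, cell_count, volume_mL, is_blank
## (the CSV schema shared with the synthetic generator). Exchange rates are
## reported in fmol/cell/h with positive = secretion, negative = consumption.

#' Blank-correct a metabolite time course
#'
#' Subtracts the cell-free drift of the blank medium from each sample series:
#' `corrected(t) = sample(t) - (blank(t) - blank(0))`. The t = 0 anchor is
#' preserved so fold changes against the starting concentration are
#' unaffected by the correction. Metabolites without a blank series are
#' passed through unchanged with a warning.
#'
#' @param ts long-format concentration table (see above) containing sample
#'   rows and, optionally, blank rows (`is_blank == TRUE`).
#' @return the sample rows with corrected `conc_mM`; attribute
#'   `blank_missing` lists metabolites that had no blank.
#' @export
blank_correct <- function(ts) {
  req <- c("metabolite", "time_h", "conc_mM", "is_blank")
  stopifnot(all(req %in% names(ts)))
  samp <- ts[!ts$is_blank, , drop = FALSE]
  blank <- ts[ts$is_blank, , drop = FALSE]
  missing <- character()
  for (m in unique(samp$metabolite)) {
    bi <- blank$metabolite == m
    if (!any(bi)) { missing <- c(missing, m); next }
    b <- blank[bi, ]
    b <- b[order(b$time_h), ]
    si <- which(samp$metabolite == m)
    drift <- stats::approx(b$time_h, b$conc_mM - b$conc_mM[b$time_h == 0][1],
                           xout = samp$time_h[si], rule = 2)$y
    samp$conc_mM[si] <- samp$conc_mM[si] - drift
  }
  if (length(missing))
    warning("no blank series for: ", paste(missing, collapse = ", "),
            " (passed through uncorrected)")
  attr(samp, "blank_missing") <- missing
  samp
}

## Integral of N(t) = N0 * exp(mu t) over [0, T], stable as mu -> 0
growth_integral <- function(n0, mu, T) {
  if (abs(mu * T) < 1e-8) n0 * T * (1 + mu * T / 2) else
    n0 * (exp(mu * T) - 1) / mu
}

#' Per-cell exchange rates from a concentration time course
#'
#' For each metabolite, the net exchange rate is the endpoint concentration
#' change scaled by culture volume and divided by the time-integrated cell
#' number: `v = dC * V / integral(N(t) dt)`, with `N(t)` interpolated
#' exponentially between the measured cell counts (the closed form
#' `N0 (exp(mu T) - 1)/mu`, with the limit `N0 T` as `mu -> 0`). Units:
#' fmol/cell/h, positive = secretion. The SD is propagated to first order
#' from the endpoint concentration SDs.
#'
#' @param ts blank-corrected sample table (see [blank_correct()]).
#' @param growth_rate optional growth rate (1/h); when NULL it is estimated
#'   from the first and last cell counts.
#' @return an `exchange_rates` data.frame: metabolite, rate, sd, log2fc.
#' @examples
#' ts <- data.frame(metabolite = "lactate", time_h = c(0, 24, 48),
#'                  conc_mM = c(1, 2, 3), conc_sd = 0.05,
#'                  cell_count = 1e5, volume_mL = 1, is_blank = FALSE)
#' exchange_rates(ts)  # 2 mM * 1 mL over 48 h at 1e5 cells
#' @export
exchange_rates <- function(ts, growth_rate = NULL) {
  req <- c("metabolite", "time_h", "conc_mM", "cell_count", "volume_mL")
  stopifnot(all(req %in% names(ts)))
  if (any(ts$cell_count <= 0)) stop("non-positive cell counts")
  out <- do.call(rbind, lapply(split(ts, ts$metabolite), function(d) {
    d <- d[order(d$time_h), ]
    if (nrow(d) < 2) stop("need >= 2 timepoints for ", d$metabolite[1])
    T <- d$time_h[nrow(d)] - d$time_h[1]
    n0 <- d$cell_count[1]
    mu <- if (!is.null(growth_rate)) growth_rate else
      log(d$cell_count[nrow(d)] / n0) / T
    int_n <- growth_integral(n0, mu, T)          # cell * h
    dC <- d$conc_mM[nrow(d)] - d$conc_mM[1]       # mM = mmol/L
    V <- d$volume_mL[1]
    ## mM * mL = umol * 1e-3 = nmol ... dC*V in 1e-6 mmol; to fmol: 1e9
    rate <- dC * V / int_n * 1e9
    sd_dC <- if ("conc_sd" %in% names(d))
      sqrt(d$conc_sd[nrow(d)]^2 + d$conc_sd[1]^2) else NA_real_
    rate_sd <- sd_dC * V / int_n * 1e9
    c0 <- d$conc_mM[1]
    l2 <- if (is.finite(c0) && c0 > 0 && d$conc_mM[nrow(d)] > 0)
      log2(d$conc_mM[nrow(d)] / c0) else NA_real_
    data.frame(metabolite = d$metabolite[1], rate = rate, sd = rate_sd,
               log2fc = l2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("exchange_rates", "data.frame")
  out
}

#' Log2 fold change at the final timepoint
#'
#' `log2(C(T) / C(0))` per metabolite. Metabolites with non-positive (below
#' quantification) starting concentration get NA rather than a fabricated
#' ratio.
#'
#' @param ts blank-corrected sample table.
#' @return data.frame with metabolite and log2fc.
#' @export
log2_fold_change <- function(ts) {
  out <- do.call(rbind, lapply(split(ts, ts$metabolite), function(d) {
    d <- d[order(d$time_h), ]
    c0 <- d$conc_mM[1]; cT <- d$conc_mM[nrow(d)]
    data.frame(metabolite = d$metabolite[1],
               log2fc = if (c0 > 0 && cT > 0) log2(cT / c0) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Convert exchange rates between per-cell and per-dry-weight units
#'
#' fmol/cell/h to mmol/gDW/h and back, with a configurable cell dry mass.
#' The round trip is an exact identity.
#'
#' @param rate numeric rates.
#' @param gdw_per_cell cell dry mass in grams (default 4e-10).
#' @return converted rates.
#' @export
fmol_cell_h_to_mmol_gdw_h <- function(rate, gdw_per_cell = 4e-10) {
  rate * 1e-12 / gdw_per_cell
}

#' @rdname fmol_cell_h_to_mmol_gdw_h
#' @export
mmol_gdw_h_to_fmol_cell_h <- function(rate, gdw_per_cell = 4e-10) {
  rate * gdw_per_cell / 1e-12
}

#' @export
print.exchange_rates <- function(x, ...) {
  cat("Exchange rates (fmol/cell/h; positive = secretion,",
      "negative = consumption)\n")
  print.data.frame(x, ...)
  invisible(x)
}
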
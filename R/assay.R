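# Reporter-assay statistics: Miller units, heat induction factors with
# replicate dispersion and Student t tests, and in vitro translation fold
# changes.

#' Miller units from a beta-galactosidase measurement
#'
#' `M.U. = 1000 * A420 / (time_min * volume_ml * OD600)`. This is the
#' A420-only variant of the Miller formula (no A550 light-scattering
#' correction), matching a protocol that records only A420; supply a
#' pre-corrected absorbance if a correction is wanted.
#'
#' @param a420 Absorbance at 420 nm (>= 0).
#' @param time_min Reaction time in minutes (> 0).
#' @param volume_ml Culture volume assayed in ml (> 0).
#' @param od600 Culture optical density at 600 nm (> 0).
#' @return Miller units (vectorized).
#' @examples
#' miller_units(0.6, 90, 0.02, 0.5)  # 666.67
#' @export
miller_units <- function(a420, time_min, volume_ml, od600) {
  if (any(a420 < 0, na.rm = TRUE)) stop("a420 must be >= 0", call. = FALSE)
  if (any(!is.finite(time_min) | time_min <= 0)) {
    stop("time_min must be > 0", call. = FALSE)
  }
  if (any(!is.finite(volume_ml) | volume_ml <= 0)) {
    stop("volume_ml must be > 0", call. = FALSE)
  }
  if (any(!is.finite(od600) | od600 <= 0)) {
    stop("od600 must be > 0", call. = FALSE)
  }
  1000 * a420 / (time_min * volume_ml * od600)
}

# per-replicate activity for one construct/assay: Miller units in vivo,
# raw A420 in vitro
.activities <- function(table, construct) {
  tb <- table[table$construct == construct, , drop = FALSE]
  if (!nrow(tb)) stop("no measurements for construct '", construct, "'",
                      call. = FALSE)
  assay <- unique(tb$assay)
  if (length(assay) != 1L) {
    stop("construct '", construct, "' mixes in_vivo and in_vitro rows",
         call. = FALSE)
  }
  act <- if (assay == "in_vivo") {
    for (col in c("od600", "volume_ml", "time_min")) {
      if (!col %in% names(tb) || anyNA(tb[[col]])) {
        stop("in_vivo rows for '", construct, "' need column '", col, "'",
             call. = FALSE)
      }
    }
    miller_units(tb$a420, tb$time_min, tb$volume_ml, tb$od600)
  } else {
    tb$a420
  }
  split(act, tb$temperature)
}

# ratio of group means with first-order (delta-method) sd of the ratio and
# an optional two-sample t test on per-replicate activities
.fold_stats <- function(hi, lo, var_equal = TRUE) {
  m_hi <- mean(hi); m_lo <- mean(lo)
  f <- m_hi / m_lo
  sd_f <- NA_real_
  p <- NA_real_; tstat <- NA_real_
  if (length(hi) >= 2L && length(lo) >= 2L) {
    se_hi2 <- stats::var(hi) / length(hi)
    se_lo2 <- stats::var(lo) / length(lo)
    sd_f <- abs(f) * sqrt(se_hi2 / m_hi^2 + se_lo2 / m_lo^2)
    near_const <- function(x) diff(range(x)) <= 1e-10 * max(abs(x), 1)
    if (near_const(hi) && near_const(lo)) {
      # dispersion-free groups (e.g. noiseless simulation): degenerate t
      tstat <- if (isTRUE(all.equal(m_hi, m_lo))) 0 else Inf * sign(m_hi - m_lo)
      p <- if (tstat == 0) 1 else 0
    } else {
      tt <- stats::t.test(hi, lo, var.equal = var_equal)
      p <- tt$p.value; tstat <- unname(tt$statistic)
    }
  }
  list(factor = f, sd = sd_f, t = tstat, p = p)
}

#' Heat induction factors for one construct
#'
#' Computes the heat induction factor — reporter activity at an elevated
#' temperature divided by activity at the reference temperature — from
#' per-replicate measurements. Activity is Miller units for `in_vivo`
#' assays and raw A420 for `in_vitro`. The factor is the ratio of group
#' means (not the mean of per-replicate ratios; the latter is also reported
#' as `factor_*_mor` if `mean_of_ratios = TRUE` and replicate counts
#' match). Dispersion is the first-order error propagation of the two group
#' means; the p-value is a two-tailed two-sample Student t test on
#' per-replicate activities (equal-variance by default, Welch via
#' `var_equal = FALSE`).
#'
#' @param table Data frame of measurements with columns `construct`,
#'   `assay` (`in_vivo`/`in_vitro`), `temperature`, `replicate`, `a420` and
#'   (in vivo) `od600`, `volume_ml`, `time_min`.
#' @param construct Construct label to summarize.
#' @param ref_temp Reference temperature (default 25).
#' @param elevated Elevated temperatures to report (default `c(37, 42)`).
#' @param var_equal Equal-variance Student t test (default) or Welch.
#' @param mean_of_ratios Also report the mean of per-replicate ratios.
#' @return One-row data frame: `construct`, `n`, and per elevated
#'   temperature `factor_T`, `sd_T`, `t_T`, `p_T`.
#' @examples
#' tb <- data.frame(construct = "wt", assay = "in_vitro",
#'                  temperature = rep(c(25, 42), each = 3), replicate = 1:3,
#'                  a420 = c(0.10, 0.11, 0.09, 0.40, 0.46, 0.52))
#' heat_induction(tb, "wt", elevated = 42)
#' @export
heat_induction <- function(table, construct, ref_temp = 25,
                           elevated = c(37, 42), var_equal = TRUE,
                           mean_of_ratios = FALSE) {
  groups <- .activities(table, construct)
  ref_key <- as.character(ref_temp)
  if (!ref_key %in% names(groups)) {
    stop("construct '", construct, "' has no measurements at the reference ",
         ref_temp, " degC", call. = FALSE)
  }
  lo <- groups[[ref_key]]
  out <- data.frame(construct = construct, n = length(lo),
                    stringsAsFactors = FALSE)
  for (tmp in elevated) {
    key <- as.character(tmp)
    suffix <- key
    if (!key %in% names(groups)) {
      stop("construct '", construct, "' has no measurements at ", tmp,
           " degC", call. = FALSE)
    }
    st <- .fold_stats(groups[[key]], lo, var_equal)
    out[[paste0("factor_", suffix)]] <- st$factor
    out[[paste0("sd_", suffix)]] <- st$sd
    out[[paste0("t_", suffix)]] <- st$t
    out[[paste0("p_", suffix)]] <- st$p
    if (mean_of_ratios) {
      hi <- groups[[key]]
      if (length(hi) == length(lo)) {
        out[[paste0("factor_", suffix, "_mor")]] <- mean(hi / lo)
      } else {
        out[[paste0("factor_", suffix, "_mor")]] <- NA_real_
      }
    }
  }
  out
}

#' In vitro translation fold changes for one construct
#'
#' Same contract as [heat_induction()] but restricted to `in_vitro` rows,
#' where activity is the raw A420 of the translation readout.
#'
#' @inheritParams heat_induction
#' @return One-row data frame as in [heat_induction()].
#' @export
in_vitro_fold <- function(table, construct, ref_temp = 25,
                          elevated = c(37, 42), var_equal = TRUE) {
  tb <- table[table$assay == "in_vitro", , drop = FALSE]
  if (!nrow(tb)) stop("no in_vitro rows in table", call. = FALSE)
  heat_induction(tb, construct, ref_temp, elevated, var_equal)
}

#' Summarize every construct in a measurement table
#'
#' @inheritParams heat_induction
#' @return Data frame with one row per construct (row-bound
#'   [heat_induction()] results).
#' @export
induction_table <- function(table, ref_temp = 25, elevated = c(37, 42),
                            var_equal = TRUE) {
  do.call(rbind, lapply(unique(table$construct), function(cn) {
    heat_induction(table, cn, ref_temp, elevated, var_equal)
  }))
}

#' Read a measurement table (TSV/CSV)
#'
#' Validates the column contract consumed by [heat_induction()]: columns
#' `construct`, `assay`, `temperature`, `replicate`, `a420` always, plus
#' `od600`, `volume_ml`, `time_min` on `in_vivo` rows.
#'
#' @param path TSV or CSV file (delimiter inferred from the extension).
#' @return Validated data frame.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("assay table not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tb <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("construct", "assay", "temperature", "replicate", "a420")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    stop("assay table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tb$assay), c("in_vivo", "in_vitro"))
  if (length(bad)) {
    stop("unknown assay type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tb$assay == "in_vivo")) {
    vivo <- tb[tb$assay == "in_vivo", ]
    for (col in c("od600", "volume_ml", "time_min")) {
      if (!col %in% names(tb) || anyNA(vivo[[col]])) {
        stop("in_vivo rows require column '", col, "'", call. = FALSE)
      }
    }
  }
  tb
}
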
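# In-line probing quantification: region normalization against invariant
# control regions and wild-type vs mutant contrasts.

#' Construct a probing lane profile
#'
#' @param intensities Numeric vector of non-negative band intensities,
#'   ordered by nucleotide position.
#' @param construct Construct label.
#' @param temperature Probing temperature in degC.
#' @return A `lane_profile`.
#' @export
lane_profile <- function(intensities, construct = "wt", temperature = 42) {
  intensities <- as.numeric(intensities)
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  structure(list(construct = construct, temperature = temperature,
                 intensities = intensities),
            class = "lane_profile")
}

#' Construct a probing region map
#'
#' Named 0-based position sets over a lane profile. `LOOP1` and
#' `REF_A48_49` are the invariant control regions used for normalization
#' (they do not change between wild-type and mutant); `ROSEG` and `SD` are
#' the regions of interest. Sets must be non-empty, disjoint and within the
#' profile.
#'
#' @param ROSEG,SD,LOOP1,REF_A48_49 Integer vectors of 0-based positions.
#' @return A `region_map` (named list).
#' @export
region_map <- function(ROSEG, SD, LOOP1, REF_A48_49) {
  rm <- list(ROSEG = as.integer(ROSEG), SD = as.integer(SD),
             LOOP1 = as.integer(LOOP1), REF_A48_49 = as.integer(REF_A48_49))
  if (any(lengths(rm) == 0L)) stop("all regions must be non-empty", call. = FALSE)
  all_pos <- unlist(rm)
  if (anyDuplicated(all_pos)) stop("regions must be disjoint", call. = FALSE)
  if (any(all_pos < 0L)) stop("positions are 0-based and must be >= 0", call. = FALSE)
  structure(rm, class = "region_map")
}

.check_regions <- function(profile, regions) {
  n <- length(profile$intensities)
  if (any(unlist(regions) >= n)) {
    stop("region positions exceed profile length (", n, ")", call. = FALSE)
  }
}

#' Normalize region intensities to the invariant control regions
#'
#' For each region, `N(region) = mean intensity over the region / mean of
#' (mean LOOP1 intensity, mean REF_A48_49 intensity)`. The reference is the
#' unweighted mean of the two control-region means, so the result is
#' invariant to global lane scaling (gel loading differences).
#'
#' @param profile A [lane_profile()].
#' @param regions A [region_map()].
#' @return Named numeric vector of normalized values, one per region
#'   (controls included; they bracket 1 by construction).
#' @export
normalize_regions <- function(profile, regions) {
  stopifnot(inherits(profile, "lane_profile"), inherits(regions, "region_map"))
  .check_regions(profile, regions)
  x <- profile$intensities
  region_mean <- vapply(regions, function(idx) mean(x[idx + 1L]), 0)
  ref <- mean(c(region_mean[["LOOP1"]], region_mean[["REF_A48_49"]]))
  if (!is.finite(ref) || ref <= 0) {
    stop("control regions have zero total intensity; cannot normalize",
         call. = FALSE)
  }
  region_mean / ref
}

#' Contrast normalized cleavage between two lanes
#'
#' Per-region ratio `N(mut) / N(wt)` of control-normalized intensities. A
#' ratio below 1 indicates reduced cleavage — i.e. a more stable, less
#' flexible backbone — in the mutant, as expected for a stabilized,
#' non-functional thermometer.
#'
#' @param wt,mut [lane_profile()] objects sharing `regions`.
#' @param regions A [region_map()].
#' @return Data frame with one row per region: `region`, `n_wt`, `n_mut`,
#'   `ratio`.
#' @export
condition_contrast <- function(wt, mut, regions) {
  n_wt <- normalize_regions(wt, regions)
  n_mut <- normalize_regions(mut, regions)
  data.frame(region = names(regions),
             n_wt = unname(n_wt), n_mut = unname(n_mut),
             ratio = unname(n_mut / n_wt),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read probing lanes from TSV
#'
#' Expected layout: a `position` column (0-based) and one intensity column
#' per lane, named `<construct>_<temperature>` (e.g. `wt_42`, `G32C_42`).
#'
#' @param path TSV file.
#' @return Named list of [lane_profile()] objects.
#' @export
read_lane_profiles <- function(path) {
  if (!file.exists(path)) stop("lane table not found: ", path, call. = FALSE)
  tb <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"position" %in% names(tb)) {
    stop("lane table needs a 'position' column", call. = FALSE)
  }
  tb <- tb[order(tb$position), , drop = FALSE]
  lanes <- setdiff(names(tb), "position")
  if (!length(lanes)) stop("lane table has no intensity columns", call. = FALSE)
  out <- lapply(lanes, function(cn) {
    parts <- strsplit(cn, "_", fixed = TRUE)[[1]]
    tmp <- suppressWarnings(as.numeric(parts[length(parts)]))
    construct <- paste(parts[-length(parts)], collapse = "_")
    if (is.na(tmp)) {
      construct <- cn
      tmp <- NA_real_
    }
    lane_profile(tb[[cn]], construct = construct, temperature = tmp)
  })
  names(out) <- lanes
  out
}

#' Write probing lanes as TSV
#'
#' @param lanes Named list of [lane_profile()] objects of equal length.
#' @param path Output path.
#' @param header Optional `#`-prefixed provenance lines.
#' @export
write_lane_profiles <- function(lanes, path, header = NULL) {
  lens <- vapply(lanes, function(l) length(l$intensities), 1L)
  stopifnot(length(unique(lens)) == 1L)
  df <- data.frame(position = seq_len(lens[1]) - 1L)
  for (nm in names(lanes)) df[[nm]] <- lanes[[nm]]$intensities
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
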
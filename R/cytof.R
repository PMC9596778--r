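#' Construct a cytometry frame
#'
#' Event-level intensity container: an events x markers matrix plus the
#' sample each event came from and the transform state, which may only move
#' forward along raw -> arcsinh -> rescaled. FCS readers can populate this
#' container; a CSV of events (marker columns + a `sample_id` column) is the
#' text-format equivalent with the same contract.
#'
#' @param intensities Events x markers numeric matrix with marker column
#'   names.
#' @param sample_id Sample label per event.
#' @param transform_state `"raw"`, `"arcsinh"` or `"rescaled"`.
#' @return Object of class `cytometry_frame`.
#' @export
cytometry_frame <- function(intensities, sample_id,
                            transform_state = c("raw", "arcsinh", "rescaled")) {
  transform_state <- match.arg(transform_state)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(colnames(intensities))) stop("marker column names required", call. = FALSE)
  if (length(sample_id) != nrow(intensities))
    stop("one sample label per event required", call. = FALSE)
  structure(list(intensities = intensities, sample_id = as.character(sample_id),
                 markers = colnames(intensities), transform_state = transform_state,
                 flagged_markers = character(0)),
            class = "cytometry_frame")
}

#' Read a cytometry event CSV
#'
#' Text fallback with the same column contract as an FCS load: one event per
#' row, marker columns, plus a `sample_id` column.
#'
#' @param path CSV/TSV path.
#' @return A raw-state [cytometry_frame()].
#' @export
read_cytometry_csv <- function(path) {
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"sample_id" %in% names(tab)) stop("cytometry CSV lacks a sample_id column", call. = FALSE)
  ints <- as.matrix(tab[, setdiff(names(tab), "sample_id"), drop = FALSE])
  cytometry_frame(ints, tab$sample_id, transform_state = "raw")
}

#' @export
print.cytometry_frame <- function(x, ...) {
  cat(sprintf("cytometry_frame [%s]: %d events x %d markers, %d samples\n",
              x$transform_state, nrow(x$intensities), length(x$markers),
              length(unique(x$sample_id))))
  invisible(x)
}

#' Arcsinh-transform raw ion intensities
#'
#' Elementwise `asinh(x / cofactor)`; the mass-cytometry convention uses a
#' cofactor of 5. Negative intensities pass through unchanged in sign.
#'
#' @param frame A raw-state [cytometry_frame()].
#' @param cofactor Positive scale divisor (default 5).
#' @return The frame in `arcsinh` state.
#' @export
arcsinh_transform <- function(frame, cofactor = 5) {
  stopifnot(inherits(frame, "cytometry_frame"))
  if (frame$transform_state != "raw")
    stop("arcsinh_transform expects a raw-state frame", call. = FALSE)
  if (cofactor <= 0) stop("cofactor must be > 0", call. = FALSE)
  frame$intensities <- asinh(frame$intensities / cofactor)
  frame$transform_state <- "arcsinh"
  frame
}

#' Rescale arcsinh intensities to [0, 1] with a percentile cap
#'
#' Per marker, the `p`-th percentile (linear-interpolation convention) is
#' taken as the maximum to exclude extreme values and the observed minimum
#' as the floor; values are clipped to that range and mapped linearly to
#' [0, 1]. Markers whose cap equals their floor become all-zero and are
#' listed in `flagged_markers`.
#'
#' @param frame An arcsinh-state [cytometry_frame()] with >= 2 events.
#' @param p Upper percentile (default 0.99).
#' @return The frame in `rescaled` state.
#' @export
percentile_rescale <- function(frame, p = 0.99) {
  stopifnot(inherits(frame, "cytometry_frame"))
  if (frame$transform_state != "arcsinh")
    stop("percentile_rescale expects an arcsinh-state frame", call. = FALSE)
  if (nrow(frame$intensities) < 2L) stop("need >= 2 events", call. = FALSE)
  caps <- apply(frame$intensities, 2L, stats::quantile, probs = p, type = 7, names = FALSE)
  floors <- apply(frame$intensities, 2L, min)
  flagged <- frame$markers[caps == floors]
  out <- frame$intensities
  for (j in seq_len(ncol(out))) {
    if (caps[j] == floors[j]) { out[, j] <- 0; next }
    v <- pmin(pmax(out[, j], floors[j]), caps[j])
    out[, j] <- (v - floors[j]) / (caps[j] - floors[j])
  }
  frame$intensities <- out
  frame$transform_state <- "rescaled"
  frame$flagged_markers <- flagged
  frame
}

#' Subsample a fixed number of events per sample
#'
#' Uniform draw without replacement within each sample, reproducible under
#' `seed`. Samples with fewer events than requested contribute all their
#' events with a warning.
#'
#' @param frame A [cytometry_frame()].
#' @param n_per_sample Events to keep per sample (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return The subsampled frame (attribute `kept_index` records the row
#'   indices kept, in order).
#' @export
subsample_per_sample <- function(frame, n_per_sample = 1000L, seed = NULL) {
  stopifnot(inherits(frame, "cytometry_frame"))
  if (!is.null(seed)) set.seed(seed)
  keep <- integer(0)
  for (s in unique(frame$sample_id)) {
    idx <- which(frame$sample_id == s)
    if (length(idx) < n_per_sample) {
      warning(sprintf("sample '%s' has %d events (< %d); keeping all", s,
                      length(idx), n_per_sample), call. = FALSE)
      keep <- c(keep, idx)
    } else if (n_per_sample > 0L) {
      keep <- c(keep, sort(idx[sample.int(length(idx), n_per_sample)]))
    }
  }
  out <- frame
  out$intensities <- frame$intensities[keep, , drop = FALSE]
  out$sample_id <- frame$sample_id[keep]
  attr(out, "kept_index") <- keep
  out
}

#' Compare per-sample cluster frequencies between groups
#'
#' Per sample, a cluster's frequency is its event count divided by the
#' sample's total events (within the declared parent population). Composite
#' populations are supported as unions of cluster labels, whose frequency is
#' the sum of member frequencies. Each population is compared between the
#' `high` and `low` sample groups by the rank-sum test.
#'
#' @param cluster Cluster label per event.
#' @param sample_id Sample label per event.
#' @param sample_groups Named vector (`high`/`low`) per sample.
#' @param populations Optional named list of label unions, e.g.
#'   `list(DP_T = c("T12","T14","T17","T24","T25"))`.
#' @return List with `frequencies` (samples x populations matrix) and
#'   `comparison` (`data.frame`: `population`, `median_high`, `median_low`,
#'   `p`).
#' @export
cluster_frequency_compare <- function(cluster, sample_id, sample_groups,
                                      populations = NULL) {
  if (length(cluster) != length(sample_id)) stop("aligned event vectors required", call. = FALSE)
  if (anyNA(cluster) || anyNA(sample_id)) stop("every event needs cluster and sample labels",
                                               call. = FALSE)
  samples <- unique(sample_id)
  grp <- sample_groups[samples]
  if (anyNA(grp)) stop("every sample needs a group label", call. = FALSE)
  if (any(table(factor(grp, levels = c("low", "high"))) < 2L))
    stop("each group needs >= 2 samples", call. = FALSE)
  counts <- table(factor(sample_id, levels = samples), factor(cluster))
  freq <- sweep(unclass(counts), 1L, rowSums(counts), "/")
  pops <- as.list(colnames(freq))
  names(pops) <- colnames(freq)
  if (!is.null(populations)) pops <- c(pops, populations)
  fr <- vapply(pops, function(members) rowSums(freq[, members, drop = FALSE]),
               numeric(nrow(freq)))
  comparison <- do.call(rbind, lapply(names(pops), function(pn) {
    v <- fr[, pn]
    data.frame(population = pn,
               median_high = stats::median(v[grp == "high"]),
               median_low = stats::median(v[grp == "low"]),
               p = two_group_test(v, grp), stringsAsFactors = FALSE)
  }))
  list(frequencies = fr, comparison = comparison)
}
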
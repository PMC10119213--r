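#' Detect apoptotic fragmentation events
#'
#' Keeps fragment candidates with calibrated area between 3 and 25 square
#' micrometers, single-linkage clusters them per slice with the given linking
#' distance (micrometers), and turns clusters with at least
#' \code{minFragments} members into apoptosis events whose center is the mean
#' of the member centroids. Each fragment belongs to at most one event;
#' fragments in no event are discarded debris.
#'
#' @param fragments fragment-candidate data.frame (id, slice, row, col,
#'   area_um2) as produced by \code{\link{filterParticles}}.
#' @param calibration a \linkS4class{PixelCalibration}.
#' @param clusterRadius single-linkage linking distance, micrometers.
#' @param minFragments minimum fragments per event.
#' @param minArea,maxArea fragment area band, square micrometers.
#' @return List with \code{events} (event_id, slice, row, col, n_fragments)
#'   and \code{fragments} (the in-band candidates with their event_id, NA if
#'   unclustered).
#' @export
detectApoptosis <- function(fragments, calibration, clusterRadius = 20,
                            minFragments = 2L, minArea = 3, maxArea = 25) {
  emptyEvents <- data.frame(event_id = integer(0), slice = integer(0),
                            row = numeric(0), col = numeric(0),
                            n_fragments = integer(0), stringsAsFactors = FALSE)
  if (is.null(fragments) || !nrow(fragments))
    return(list(events = emptyEvents, fragments = emptyFragmentTable()))
  fr <- fragments[fragments$area_um2 >= minArea & fragments$area_um2 <= maxArea, ,
                  drop = FALSE]
  fr[["event_id"]] <- rep(NA_integer_, nrow(fr))
  if (!nrow(fr)) return(list(events = emptyEvents, fragments = fr))
  xy <- calibration@xySize
  evs <- list(); nextEv <- 1L
  for (s in unique(fr$slice)) {
    idx <- which(fr$slice == s)
    if (length(idx) == 1) {
      if (minFragments <= 1) {
        fr$event_id[idx] <- nextEv
        evs[[nextEv]] <- data.frame(event_id = nextEv, slice = as.integer(s),
                                    row = fr$row[idx], col = fr$col[idx],
                                    n_fragments = 1L, stringsAsFactors = FALSE)
        nextEv <- nextEv + 1L
      }
      next
    }
    pts <- cbind(fr$row[idx], fr$col[idx]) * xy
    cl <- cutree(hclust(dist(pts), method = "single"), h = clusterRadius)
    for (g in unique(cl)) {
      mem <- idx[cl == g]
      if (length(mem) < minFragments) next
      fr$event_id[mem] <- nextEv
      evs[[nextEv]] <- data.frame(event_id = nextEv, slice = as.integer(s),
                                  row = mean(fr$row[mem]), col = mean(fr$col[mem]),
                                  n_fragments = length(mem),
                                  stringsAsFactors = FALSE)
      nextEv <- nextEv + 1L
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else emptyEvents
  list(events = events, fragments = fr)
}

#' Cell-death frequency per zone
#'
#' Each apoptosis event stands for one dead cell; the frequency is
#' events / (events + intact nuclei) within the zone scope. Returns 0 with a
#' warning when both counts are zero.
#'
#' @param events events data.frame with a \code{zone} column.
#' @param nuclei nucleus records with a \code{zone} column.
#' @param zone zone label ("core", "rim", "invasion") or "all".
#' @return Fraction in [0, 1].
#' @export
deathFrequency <- function(events, nuclei, zone = "invasion") {
  nE <- if (zone == "all") nrow(events) else sum(events$zone == zone)
  nN <- if (zone == "all") nrow(nuclei) else sum(nuclei$zone == zone)
  if (nE + nN == 0) {
    warning("no events and no nuclei in zone '", zone, "'; death frequency set to 0")
    return(0)
  }
  nE / (nE + nN)
}

#' Ingest manual mitosis annotations
#'
#' Annotations (slice, row, col) are validated against the image bounds
#' (out-of-bounds rows are rejected with a warning), duplicates within 5
#' micrometers on the same slice collapse to one with a warning, and each
#' mitosis is assigned a zone by its pixel. Frequencies are
#' mitoses / (mitoses + nuclei) per zone.
#'
#' @param annotations data.frame with columns slice, row, col and optionally
#'   label (must be "mitosis" when present).
#' @param zoneMap a \linkS4class{ZoneMap}.
#' @param nuclei nucleus records with a \code{zone} column.
#' @param calibration a \linkS4class{PixelCalibration}.
#' @return List with \code{mitoses} (deduplicated, zone-assigned),
#'   \code{counts} and \code{frequency} per zone.
#' @export
ingestMitoses <- function(annotations, zoneMap, nuclei, calibration) {
  zones <- c("core", "rim", "invasion")
  emptyCounts <- stats::setNames(rep(0L, 3), zones)
  if (is.null(annotations) || !nrow(annotations)) {
    freq <- stats::setNames(rep(0, 3), zones)
    return(list(mitoses = data.frame(slice = integer(0), row = numeric(0),
                                     col = numeric(0), zone = character(0)),
                counts = emptyCounts, frequency = freq))
  }
  if (!is.null(annotations$label) &&
      !all(annotations$label %in% "mitosis"))
    sqStop("sqFormatError", "annotation labels must be 'mitosis'")
  nr <- nrow(zoneMap@labels); nc <- ncol(zoneMap@labels)
  inB <- annotations$row >= 0 & annotations$row <= nr - 1 &
    annotations$col >= 0 & annotations$col <= nc - 1
  if (any(!inB)) {
    warning(sum(!inB), " mitosis annotation(s) outside the image rejected")
    annotations <- annotations[inB, , drop = FALSE]
  }
  # collapse duplicates within 5 um on the same slice (greedy, row order)
  keep <- rep(TRUE, nrow(annotations))
  xy <- calibration@xySize
  for (i in seq_len(nrow(annotations))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(annotations)) > i &
                 annotations$slice == annotations$slice[i])
    if (!length(j)) next
    d <- sqrt((annotations$row[j] - annotations$row[i])^2 +
                (annotations$col[j] - annotations$col[i])^2) * xy
    dup <- j[d < 5]
    if (length(dup)) {
      warning(length(dup), " duplicate mitosis annotation(s) within 5 um collapsed")
      keep[dup] <- FALSE
    }
  }
  mit <- annotations[keep, , drop = FALSE]
  mit <- assignZones(mit, zoneMap)
  counts <- vapply(zones, function(z) sum(mit$zone == z), integer(1))
  nNuc <- vapply(zones, function(z) sum(nuclei$zone == z), integer(1))
  freq <- ifelse(counts + nNuc > 0, counts / (counts + nNuc), 0)
  list(mitoses = mit, counts = counts, frequency = freq)
}

#' Summarize one specimen and time point
#'
#' Fills a \linkS4class{QuantResult}: nucleus counts per (slice, zone) and
#' per zone (total and mean per slice), pooled death frequency per zone,
#' mitosis frequency per zone, and the invasion distance summary (maximum,
#' 95th percentile, median of the radial distances of invasion-zone nuclei).
#'
#' @param nuclei zone-assigned nucleus records.
#' @param events zone-assigned apoptosis events.
#' @param mitoses result of \code{\link{ingestMitoses}} or NULL.
#' @param zoneMap a \linkS4class{ZoneMap}.
#' @param quadrant a \linkS4class{QuadrantSelection} or NULL.
#' @param calibration a \linkS4class{PixelCalibration}.
#' @param timeLabel free-text time label.
#' @param snr an \linkS4class{SNRProfile} or NULL.
#' @param fragments fragment table (kept for provenance).
#' @param params parameter list echoed into the run metadata.
#' @return A \linkS4class{QuantResult}.
#' @export
summarizeQuantification <- function(nuclei, events, mitoses = NULL, zoneMap,
                                    quadrant = NULL, calibration,
                                    timeLabel = "", snr = NULL,
                                    fragments = NULL, params = list()) {
  zones <- c("core", "rim", "invasion")
  if (is.null(nuclei) || !nrow(nuclei)) nuclei <- emptyNucleusTable()
  if (is.null(fragments)) fragments <- emptyFragmentTable()
  if (is.null(events) || !nrow(events))
    events <- data.frame(event_id = integer(0), slice = integer(0),
                         row = numeric(0), col = numeric(0),
                         n_fragments = integer(0), zone = character(0))
  slices <- sort(unique(nuclei$slice))
  if (!length(slices)) slices <- integer(0)
  szc <- expand.grid(slice = slices, zone = zones, stringsAsFactors = FALSE)
  if (nrow(szc))
    szc$n_nuclei <- mapply(function(s, z) sum(nuclei$slice == s & nuclei$zone == z),
                           szc$slice, szc$zone)
  else szc$n_nuclei <- integer(0)
  nSl <- max(1L, length(slices))
  zs <- data.frame(zone = zones, stringsAsFactors = FALSE)
  zs$total_nuclei <- vapply(zones, function(z) sum(nuclei$zone == z), numeric(1))
  zs$mean_per_slice <- zs$total_nuclei / nSl
  zs$n_events <- vapply(zones, function(z)
    if (nrow(events)) sum(events$zone == z) else 0, numeric(1))
  zs$death_frequency <- ifelse(zs$n_events + zs$total_nuclei > 0,
                               zs$n_events / (zs$n_events + zs$total_nuclei), 0)
  if (!is.null(mitoses)) {
    zs$n_mitoses <- as.numeric(mitoses$counts[zones])
    zs$mitosis_frequency <- as.numeric(mitoses$frequency[zones])
    mitTab <- mitoses$mitoses
  } else {
    zs$n_mitoses <- 0; zs$mitosis_frequency <- 0
    mitTab <- data.frame(slice = integer(0), row = numeric(0), col = numeric(0),
                         zone = character(0))
  }
  invD <- nuclei$radial_um[nuclei$zone == "invasion"]
  invSum <- if (length(invD))
    list(n = length(invD), max_um = max(invD),
         q95_um = unname(quantile(invD, 0.95)), median_um = median(invD))
  else list(n = 0L, max_um = 0, q95_um = 0, median_um = 0)
  new("QuantResult", nuclei = nuclei, fragments = fragments, events = events,
      mitoses = mitTab, sliceZoneCounts = szc, zoneSummary = zs,
      invasionSummary = invSum, snr = snr, timeLabel = timeLabel,
      params = params)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided Mann-Whitney U comparison. For \code{n1 + n2 <= 12} the p-value
#' is exact: all C(n1+n2, n1) assignments of the observed mid-ranks to group
#' A are enumerated, and p is the fraction of assignments whose U deviates
#' from its mean n1 n2 / 2 at least as much as the observed U. Larger samples
#' use the normal approximation with tie correction and continuity
#' correction. The method used is recorded on the result.
#'
#' @param groupA,groupB numeric vectors (non-empty).
#' @param labels group labels for reporting.
#' @return A \linkS4class{ComparisonResult}.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mannWhitney <- function(groupA, groupB, labels = c("A", "B")) {
  if (!length(groupA) || !length(groupB))
    sqStop("sqParamError", "both groups must be non-empty")
  n1 <- length(groupA); n2 <- length(groupB)
  rk <- rank(c(groupA, groupB))  # mid-ranks for ties
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 12) {
    combs <- combn(n1 + n2, n1)
    Us <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    pv <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) { pv <- 1 } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      pv <- min(1, 2 * pnorm(-max(0, z)))
    }
    method <- "normal approximation"
  }
  new("ComparisonResult", labels = labels, values = list(groupA, groupB),
      U = U, pValue = pv, method = method)
}
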
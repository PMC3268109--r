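# AHA 16-segment model: sector definitions and 3D adjacency.

#' AHA 16-segment definition table
#'
#' Sixteen left-ventricular segments on three short-axis levels: six basal,
#' six mid-ventricular (60 degree sectors) and four apical (90 degree
#' sectors).  Angles are measured counter-clockwise in degrees with the
#' anterior wall centred at 90 degrees, i.e. the sector boundaries are
#' referenced to the anterior RV insertion at 60 degrees.  The true apex cap
#' (segment 17) is not modelled.
#'
#' @return data.frame with columns \code{segment_id}, \code{name},
#'   \code{level} (basal/mid/apical), \code{level_index} (1..3, base to
#'   apex), \code{theta_start}, \code{theta_end} (degrees, sector spans
#'   \code{[theta_start, theta_end)} going counter-clockwise).
#' @export
#' @examples
#' segs <- aha_segments()
#' stopifnot(nrow(segs) == 16L)
aha_segments <- function() {
  base_names <- c("anterior", "anteroseptal", "inferoseptal",
                  "inferior", "inferolateral", "anterolateral")
  base_start <- c(60, 120, 180, 240, 300, 0)
  ap_names <- c("anterior", "septal", "inferior", "lateral")
  ap_start <- c(45, 135, 225, 315)
  data.frame(
    segment_id  = 1:16,
    name = c(paste0("basal_", base_names), paste0("mid_", base_names),
             paste0("apical_", ap_names)),
    level = c(rep("basal", 6), rep("mid", 6), rep("apical", 4)),
    level_index = c(rep(1L, 6), rep(2L, 6), rep(3L, 4)),
    theta_start = c(base_start, base_start, ap_start),
    theta_end = c(base_start + 60, base_start + 60, ap_start + 90),
    stringsAsFactors = FALSE
  )
}

# Angular overlap (degrees) of two circular sectors given as [start, end).
sector_overlap_deg <- function(s1, e1, s2, e2) {
  # unroll onto [0, 720) to handle wrap-around
  a <- c(s1, e1) %% 360
  b <- c(s2, e2) %% 360
  if (a[2] <= a[1]) a[2] <- a[2] + 360
  if (b[2] <= b[1]) b[2] <- b[2] + 360
  ov <- 0
  for (shift in c(-360, 0, 360)) {
    lo <- max(a[1], b[1] + shift)
    hi <- min(a[2], b[2] + shift)
    ov <- ov + max(0, hi - lo)
  }
  ov
}

#' Default 3D adjacency of the 16 AHA segments
#'
#' Two segments are adjacent when they are circumferential neighbours on the
#' same level, or when they sit on consecutive levels and their angular
#' sectors overlap by at least \code{min_overlap_deg}.  Basal and mid rings
#' (6 vs 6 sectors) pair one-to-one; mid and apical rings (6 vs 4) pair by
#' sector overlap.  Used by \code{\link{classify_segments}} to find
#' peri-infarct segments ("immediately adjacent in 3D").
#'
#' @param min_overlap_deg minimum angular overlap (degrees) for an
#'   inter-level edge; default 30.
#' @return object of class \code{aha_adjacency}: a symmetric 16 x 16 logical
#'   matrix with attribute \code{edges} (two-column matrix of segment id
#'   pairs, i < j).
#' @export
default_adjacency <- function(min_overlap_deg = 30) {
  segs <- aha_segments()
  adj <- matrix(FALSE, 16, 16)
  for (i in 1:15) {
    for (j in (i + 1):16) {
      li <- segs$level_index[i]; lj <- segs$level_index[j]
      if (li == lj) {
        # ring neighbours: sectors sharing a boundary
        d <- ang_dist_deg(segs$theta_start[i], segs$theta_end[j])
        d2 <- ang_dist_deg(segs$theta_end[i], segs$theta_start[j])
        if (min(d, d2) < 1e-9) adj[i, j] <- TRUE
      } else if (abs(li - lj) == 1L) {
        ov <- sector_overlap_deg(segs$theta_start[i], segs$theta_end[i],
                                 segs$theta_start[j], segs$theta_end[j])
        if (ov >= min_overlap_deg) adj[i, j] <- TRUE
      }
    }
  }
  adj <- adj | t(adj)
  dimnames(adj) <- list(segs$segment_id, segs$segment_id)
  e <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  structure(adj, edges = cbind(e[, 1], e[, 2]), class = "aha_adjacency")
}

#' Neighbours of a segment in the adjacency graph
#' @param adjacency an \code{aha_adjacency} matrix
#' @param segment_id segment id (1..16)
#' @return integer vector of neighbouring segment ids
#' @export
segment_neighbors <- function(adjacency, segment_id) {
  which(unclass(adjacency)[segment_id, ])
}
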
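# Segment, label, measure and filter 3D objects to identify asbestos
# bodies: the automated counting workflow (segmentation -> size filter ->
# sphericity/solidity/aspect-ratio filters), run in full 3D.

#' Segmentation parameters
#'
#' Inclusive grey-level range defining foreground. Physically, grey level
#' tracks material density, so a band `[grey_lo, grey_hi]` selects the
#' high-absorbing phases (AB and other particulate) against tissue and
#' air. The band depends on the acquisition setup and must be calibrated
#' per instrument; it is always explicit configuration, never a hidden
#' constant.
#'
#' @param grey_lo,grey_hi inclusive foreground bounds, `grey_lo <= grey_hi`.
#' @return An object of class `ab_segmentation_params`.
#' @export
segmentation_params <- function(grey_lo = 0.6, grey_hi = 2.0) {
  if (!is.finite(grey_lo) || is.na(grey_hi) || grey_lo > grey_hi)
    stop("require finite grey_lo <= grey_hi")
  structure(list(grey_lo = grey_lo, grey_hi = grey_hi),
            class = "ab_segmentation_params")
}

#' Shape and size filter parameters
#'
#' Thresholds of the object filters: voxel-count bounds exclude small
#' particulate and large dense structures; the sphericity cap and
#' solidity floor select elongated, quasi-cylindrical objects; the
#' aspect-ratio rule keeps only objects more than `min_aspect_ratio`
#' times longer than wide. Defaults are phantom-calibrated working
#' values, not instrument constants.
#'
#' @param min_size_vox,max_size_vox inclusive component voxel-count bounds.
#' @param max_sphericity maximum shortest/longest principal-extent ratio,
#'   in `(0, 1]`.
#' @param min_solidity minimum object/convex-hull volume ratio, in
#'   `(0, 1]`.
#' @param min_aspect_ratio objects are accepted only when
#'   `aspect_ratio > min_aspect_ratio` (strict), default 3.
#' @param connectivity 6, 18 or 26 (default 26: thin oblique fibres
#'   fragment under 6-connectivity).
#' @param border_policy `"include"` or `"exclude"` objects touching the
#'   volume faces.
#' @return An object of class `ab_filter_params`.
#' @export
filter_params <- function(min_size_vox = 200L, max_size_vox = 2e5,
                          max_sphericity = 0.5, min_solidity = 0.5,
                          min_aspect_ratio = 3, connectivity = 26L,
                          border_policy = c("include", "exclude")) {
  if (min_size_vox < 1L) stop("min_size_vox must be >= 1")
  if (min_size_vox > max_size_vox)
    stop("min_size_vox must not exceed max_size_vox")
  if (max_sphericity <= 0 || max_sphericity > 1)
    stop("max_sphericity must lie in (0, 1]")
  if (min_solidity <= 0 || min_solidity > 1)
    stop("min_solidity must lie in (0, 1]")
  if (min_aspect_ratio < 1) stop("min_aspect_ratio must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  border_policy <- match.arg(border_policy)
  structure(list(min_size_vox = as.integer(min_size_vox),
                 max_size_vox = max_size_vox,
                 max_sphericity = max_sphericity,
                 min_solidity = min_solidity,
                 min_aspect_ratio = min_aspect_ratio,
                 connectivity = as.integer(connectivity),
                 border_policy = border_policy),
            class = "ab_filter_params")
}

#' Grey-level segmentation
#'
#' A voxel is foreground iff `grey_lo <= value <= grey_hi`.
#'
#' @param volume an [volume()] object.
#' @param params an [segmentation_params()] object.
#' @return Logical array of the volume's shape.
#' @export
segment <- function(volume, params) {
  stopifnot(inherits(volume, "ab_volume"),
            inherits(params, "ab_segmentation_params"))
  volume$data >= params$grey_lo & volume$data <= params$grey_hi
}

#' Label 3D connected components
#'
#' Maximal connected components of a binary mask under 6-, 18- or
#' 26-connectivity. Labels are dense from 1; background is 0.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of labels with attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3D array")
  if (anyNA(mask)) stop("mask must not contain NA")
  .label3d_cpp(mask, dim(mask), as.integer(connectivity))
}

# coordinates of each labelled component, as a list of n x 3 index
# matrices in label order
.component_voxel_sets <- function(labels) {
  n <- attr(labels, "n_components")
  if (is.null(n)) n <- max(labels)
  if (n == 0L) return(list())
  idx <- which(labels > 0L)
  labv <- labels[idx]
  coords <- arrayInd(idx, dim(labels))
  ord <- order(labv)
  cnt <- tabulate(labv, n)
  ends <- cumsum(cnt)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(n), function(k)
    coords[ord[starts[k]:ends[k]], , drop = FALSE])
}

# reduce a voxel set to cube corners that can be hull vertices: a hull
# vertex must come from a voxel that is extreme along one of the three
# axis-parallel line families through it
.hull_corner_points <- function(vox) {
  n <- nrow(vox)
  keep <- logical(n)
  for (a in 1:3) {
    oth <- setdiff(1:3, a)
    key <- vox[, oth[1]] * (max(vox[, oth[2]]) + 1) + vox[, oth[2]]
    ord <- order(key, vox[, a])
    keep[ord[!duplicated(key[ord])]] <- TRUE
    keep[ord[rev(!duplicated(rev(key[ord])))]] <- TRUE
  }
  sel <- vox[keep, , drop = FALSE]
  m <- nrow(sel)
  off <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  pts <- sel[rep(seq_len(m), each = 8L), , drop = FALSE] +
    off[rep(1:8, m), , drop = FALSE]
  key <- (pts[, 1] * 2 + 1e4) * 1e9 + (pts[, 2] * 2 + 1e4) * 1e4 +
    (pts[, 3] * 2 + 1e4)
  pts[!duplicated(key), , drop = FALSE]
}

# Eigenvectors of a covariance matrix with degenerate (repeated)
# eigenvalues snapped, within each degenerate subspace, to the nearest
# coordinate axes. Repeated eigenvalues make the eigenbasis arbitrary up
# to rotation, and an arbitrary rotation inflates max-min extents (a
# solid box would report its face diagonal as width); axis-snapping
# restores the natural basis for axis-aligned symmetric objects and is a
# no-op when eigenvalues are distinct.
.principal_axes <- function(S, tol = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors
  scale <- max(abs(vals), .Machine$double.eps)
  grp <- cumsum(c(TRUE, -diff(vals) > tol * scale))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) < 2L) next
    V <- vecs[, cols, drop = FALSE]
    P <- V %*% t(V)                       # projector onto the subspace
    axes <- order(diag(P), decreasing = TRUE)[seq_along(cols)]
    B <- P[, axes, drop = FALSE]          # axes projected into subspace
    vecs[, cols] <- qr.Q(qr(B))
  }
  vecs
}

#' Measure the shape descriptors of one voxel component
#'
#' Principal axes come from the eigenvectors of the voxel-centre
#' covariance; the extent along each axis is (max - min projection of
#' voxel centres) + 1 voxel, so a single voxel has extent one voxel.
#' Length is the longest principal extent, width the mean of the two
#' shorter ones, sphericity the shortest/longest ratio, and solidity the
#' voxel volume over the volume of the convex hull of the voxel cube
#' corners (corners, not centres, so digitized convex solids report
#' solidity 1, never above).
#'
#' @param voxels n x 3 integer matrix of 1-based voxel indices
#'   (row, col, plane), local to the grid being measured.
#' @param voxel_size isotropic voxel size in micrometres.
#' @param offset 0-based voxel offset of the grid within the full volume.
#' @param volume_extents extents of the full volume, for the
#'   border-touching flag; `NULL` disables the flag.
#' @param label label id to record.
#' @return One-row data.frame of object features.
#' @export
measure_object <- function(voxels, voxel_size, offset = c(0L, 0L, 0L),
                           volume_extents = NULL, label = 1L) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3L)
  n <- nrow(voxels)
  if (n == 0L) stop("voxel set must be non-empty")
  global <- sweep(voxels, 2L, as.numeric(offset), "+")
  centres <- (global - 0.5) * voxel_size
  if (n > 1L) {
    vecs <- .principal_axes(cov(centres))
    proj <- centres %*% vecs
    extents <- apply(proj, 2L, function(p) diff(range(p))) + voxel_size
  } else {
    extents <- rep(voxel_size, 3L)
  }
  extents <- sort(extents, decreasing = TRUE)
  len <- extents[1]
  wid <- (extents[2] + extents[3]) / 2
  hull_vox <- .hull_volume_cpp(.hull_corner_points(voxels))
  solidity <- if (hull_vox > 0) min(1, n / hull_vox) else 1
  touches <- FALSE
  if (!is.null(volume_extents))
    touches <- any(global == 1L) ||
      any(sweep(global, 2L, as.numeric(volume_extents), "==") )
  ctr <- colMeans(centres)
  data.frame(
    label = label, voxel_count = n, volume_um3 = n * voxel_size^3,
    cx_um = ctr[1], cy_um = ctr[2], cz_um = ctr[3],
    length_um = len, width_um = wid, aspect_ratio = len / wid,
    sphericity = extents[3] / extents[1], solidity = solidity,
    touches_border = touches
  )
}

# vectorised filter cascade; first failing rule is the reason, in the
# fixed order size -> sphericity -> solidity -> aspect_ratio -> border
.classify_features <- function(feat, params) {
  n <- nrow(feat)
  reason <- rep(NA_character_, n)
  fail <- function(cond, code) ifelse(is.na(reason) & cond, code, reason)
  reason <- fail(feat$voxel_count < params$min_size_vox |
                   feat$voxel_count > params$max_size_vox, "size")
  reason <- fail(feat$sphericity > params$max_sphericity, "sphericity")
  reason <- fail(feat$solidity < params$min_solidity, "solidity")
  reason <- fail(feat$aspect_ratio <= params$min_aspect_ratio,
                 "aspect_ratio")
  if (params$border_policy == "exclude")
    reason <- fail(feat$touches_border, "border")
  data.frame(status = ifelse(is.na(reason), "accepted", "rejected"),
             reason = ifelse(is.na(reason), "", reason))
}

#' Classify one measured object against the filter cascade
#'
#' Accepted iff the voxel count lies within the size bounds, sphericity
#' does not exceed `max_sphericity`, solidity is at least `min_solidity`,
#' the aspect ratio strictly exceeds `min_aspect_ratio`, and the border
#' policy is satisfied. The first failing rule (in that fixed order) is
#' recorded as the rejection reason, so reason codes are deterministic.
#'
#' @param features one-row data.frame from [measure_object()].
#' @param params an [filter_params()] object.
#' @return List with `status` (`"accepted"`/`"rejected"`) and `reason`
#'   (`""` when accepted).
#' @export
classify_object <- function(features, params) {
  stopifnot(inherits(params, "ab_filter_params"))
  cl <- .classify_features(features, params)
  list(status = cl$status[1], reason = cl$reason[1])
}

.empty_features <- function() {
  data.frame(label = integer(0), voxel_count = integer(0),
             volume_um3 = numeric(0), cx_um = numeric(0),
             cy_um = numeric(0), cz_um = numeric(0),
             length_um = numeric(0), width_um = numeric(0),
             aspect_ratio = numeric(0), sphericity = numeric(0),
             solidity = numeric(0), touches_border = logical(0),
             status = character(0), reason = character(0))
}

.detect_one <- function(vol, seg, filt, offset, full_extents) {
  mask <- segment(vol, seg)
  labels <- label_components(mask, filt$connectivity)
  sets <- .component_voxel_sets(labels)
  if (length(sets) == 0L)
    return(list(feat = .empty_features()[, 1:12], n_fg = sum(mask)))
  feat <- do.call(rbind, lapply(seq_along(sets), function(k)
    measure_object(sets[[k]], vol$voxel_size, offset = offset,
                   volume_extents = full_extents, label = k)))
  list(feat = feat, n_fg = sum(mask))
}

#' Detect asbestos bodies in a volume
#'
#' End-to-end composition of [segment()], [label_components()],
#' [measure_object()] and the filter cascade over the whole volume.
#' Counting is performed in 3D, never on projections. With
#' `n_chunks > 1` the volume is split along the plane axis into
#' overlapping chunks processed independently; each object is counted
#' exactly once, by the chunk that owns its centroid, and overlap at
#' least as large as the longest expected object guarantees the owning
#' chunk contains the object entirely, so chunked and whole-volume
#' results agree exactly.
#'
#' @param volume an [volume()] object.
#' @param seg an [segmentation_params()] object.
#' @param filt an [filter_params()] object.
#' @param n_chunks number of chunks along the plane axis (1 = whole
#'   volume).
#' @param overlap_vox planes shared between consecutive chunks; default
#'   `ceiling(50 / voxel_size)`, i.e. a 50 um bound on object length.
#' @param verbose log per-stage object counts.
#' @return An object of class `ab_table`: `objects` (all components with
#'   features, status and rejection reason), `accepted` (the accepted
#'   subset), `V_c_cm3`, `voxel_size`, `params` and `stages` (per-stage
#'   counts).
#' @export
detect_ab <- function(volume, seg = segmentation_params(),
                      filt = filter_params(), n_chunks = 1L,
                      overlap_vox = NULL, verbose = FALSE) {
  stopifnot(inherits(volume, "ab_volume"))
  d <- dim(volume$data)
  if (n_chunks <= 1L) {
    res <- .detect_one(volume, seg, filt, offset = volume$offset,
                       full_extents = d)
    feat <- res$feat
    n_fg <- res$n_fg
  } else {
    if (is.null(overlap_vox))
      overlap_vox <- ceiling(50 / volume$voxel_size)
    k <- as.integer(n_chunks)
    ext3 <- ceiling((d[3] + (k - 1) * overlap_vox) / k)
    chunks <- split_volume(volume, c(d[1], d[2], ext3),
                           overlap = overlap_vox)
    man <- attr(chunks, "manifest")
    s <- man$off_plane + 1L          # global start plane, 1-based
    e <- man$off_plane + man$ext_plane
    lo <- c(0.5, (s[-1] + e[-length(e)]) / 2)
    hi <- c((s[-1] + e[-length(e)]) / 2, d[3] + 0.5)
    feat <- NULL
    n_fg <- 0L
    for (i in seq_along(chunks)) {
      res <- .detect_one(chunks[[i]], seg, filt,
                         offset = chunks[[i]]$offset, full_extents = d)
      f <- res$feat
      if (nrow(f) > 0) {
        cz_vox <- f$cz_um / volume$voxel_size + 0.5
        f <- f[cz_vox > lo[i] & cz_vox <= hi[i], , drop = FALSE]
      }
      feat <- rbind(feat, f)
      n_fg <- n_fg + res$n_fg
    }
    if (nrow(feat) > 0) {
      feat <- feat[order(feat$cz_um, feat$cy_um, feat$cx_um), ,
                   drop = FALSE]
      feat$label <- seq_len(nrow(feat))
      rownames(feat) <- NULL
    }
  }
  if (nrow(feat) == 0L) {
    objects <- .empty_features()
  } else {
    objects <- cbind(feat, .classify_features(feat, filt))
  }
  accepted <- objects[objects$status == "accepted", , drop = FALSE]
  stages <- list(
    foreground_voxels = n_fg,
    components = nrow(objects),
    after_size = sum(!objects$reason %in% "size"),
    after_shape = sum(!objects$reason %in% c("size", "sphericity",
                                             "solidity")),
    accepted = nrow(accepted)
  )
  if (verbose)
    message(sprintf(
      "segmented %d voxels -> %d components -> %d after size -> %d after shape -> %d accepted",
      stages$foreground_voxels, stages$components, stages$after_size,
      stages$after_shape, stages$accepted))
  structure(list(objects = objects, accepted = accepted,
                 V_c_cm3 = physical_volume_cm3(volume),
                 voxel_size = volume$voxel_size,
                 params = list(segmentation = unclass(seg),
                               filter = unclass(filt)),
                 stages = stages),
            class = "ab_table")
}

#' @export
print.ab_table <- function(x, ...) {
  cat(sprintf("<ab_table> %d accepted / %d components in V_c = %.4g cm^3\n",
              nrow(x$accepted), nrow(x$objects), x$V_c_cm3))
  if (nrow(x$accepted) > 0)
    cat(sprintf("  mean length %.2f um, mean width %.2f um, density %.3g cm^-3\n",
                mean(x$accepted$length_um), mean(x$accepted$width_um),
                nrow(x$accepted) / x$V_c_cm3))
  invisible(x)
}

#' Write the per-object morphometry table as CSV
#'
#' One row per labelled component, accepted or rejected, with its
#' descriptors and rejection reason.
#'
#' @param ab_table an `ab_table` from [detect_ab()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(ab_table, path) {
  stopifnot(inherits(ab_table, "ab_table"))
  cols <- c("label", "status", "reason", "voxel_count", "volume_um3",
            "length_um", "width_um", "aspect_ratio", "sphericity",
            "solidity", "cx_um", "cy_um", "cz_um", "touches_border")
  df <- ab_table$objects
  df <- df[, cols[cols %in% names(df)], drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Match accepted detections to ground-truth fibres
#'
#' Greedy nearest-centroid matching within `max_dist_um`, for phantom
#' recovery studies: returns sensitivity (matched truths / all truths)
#' and false-discovery rate (unmatched detections / all detections).
#'
#' @param ab_table an `ab_table` from [detect_ab()].
#' @param records ground-truth data.frame.
#' @param max_dist_um maximum centroid distance for a match.
#' @return List with `n_truth`, `n_detected`, `tp`, `fn`, `fp`,
#'   `sensitivity`, `fdr`, and `pairs` (matched index pairs).
#' @export
match_truth <- function(ab_table, records, max_dist_um = 5) {
  stopifnot(inherits(ab_table, "ab_table"))
  det <- ab_table$accepted
  nt <- nrow(records); nd <- nrow(det)
  if (nt == 0L || nd == 0L)
    return(list(n_truth = nt, n_detected = nd, tp = 0L, fn = nt, fp = nd,
                sensitivity = if (nt == 0L) NA_real_ else 0,
                fdr = if (nd == 0L) NA_real_ else 1,
                pairs = data.frame(truth = integer(0),
                                   detection = integer(0))))
  dmat <- outer(records$cx_um, det$cx_um, "-")^2 +
    outer(records$cy_um, det$cy_um, "-")^2 +
    outer(records$cz_um, det$cz_um, "-")^2
  dmat <- sqrt(dmat)
  pairs <- NULL
  repeat {
    m <- which.min(dmat)
    if (dmat[m] > max_dist_um || !is.finite(dmat[m])) break
    i <- (m - 1) %% nt + 1
    j <- (m - 1) %/% nt + 1
    pairs <- rbind(pairs, data.frame(truth = i, detection = j))
    dmat[i, ] <- Inf
    dmat[, j] <- Inf
    if (all(!is.finite(dmat))) break
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  list(n_truth = nt, n_detected = nd, tp = tp, fn = nt - tp, fp = nd - tp,
       sensitivity = tp / nt, fdr = (nd - tp) / nd,
       pairs = if (is.null(pairs))
         data.frame(truth = integer(0), detection = integer(0)) else pairs)
}
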
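#' Decision thresholds for wheal-pattern classification
#'
#' The morphological taxonomy (uniform coverage, fine dots, dots, large /
#' small / broken annular, circular) is inherently visual; these thresholds
#' are a reproducible surrogate.  All lengths in millimetres.
#'
#' @param uniform_coverage coverage fraction at or above which the mask is
#'   "uniform".
#' @param dots_min_components minimum component count for a dots-type label.
#' @param fine_diam_mm median equivalent diameter below which dots are
#'   "fine".
#' @param dots_diam_mm median diameter below which a dots label applies.
#' @param big_diam_mm components at least this large enter the ring/arc/disk
#'   analysis.
#' @param ring_fill_excess a component is a ring when hole-filling grows its
#'   area by at least this fraction.
#' @param annular_fraction fraction of large components that must be rings
#'   for an annular label.
#' @param large_outer_mm median outer diameter separating large from small
#'   annular.
#' @param arc_solidity solidity below which a hole-free component counts as
#'   an arc fragment.
#' @param disk_solidity solidity at or above which a hole-free component
#'   counts as a filled disk.
#' @return A list of thresholds.
#' @export
patternRules <- function(uniform_coverage = 0.9, dots_min_components = 20,
                         fine_diam_mm = 3, dots_diam_mm = 8, big_diam_mm = 5,
                         ring_fill_excess = 0.2, annular_fraction = 0.5,
                         large_outer_mm = 20, arc_solidity = 0.5,
                         disk_solidity = 0.9) {
  as.list(environment())
}

# per-component morphology via EBImage connected components
.componentStats <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  ncomp <- max(lab)
  if (ncomp == 0) return(NULL)
  out <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    comp <- lab == k
    area <- sum(comp)
    filled <- EBImage::fillHull(matrix(as.numeric(comp), nrow(comp), ncol(comp)))
    filled_area <- sum(filled)
    idx <- which(comp, arr.ind = TRUE)
    sol <- .pixelSolidity(idx, area)
    out[[k]] <- c(area = area, filled_area = filled_area, solidity = sol)
  }
  do.call(rbind, out)
}

# solidity = pixel area / convex hull area (hull area corrected by half the
# hull perimeter + 1 so single pixels and thin shapes behave sensibly)
.pixelSolidity <- function(idx, area) {
  if (nrow(idx) <= 2) return(1)
  hull <- grDevices::chull(idx[, 1], idx[, 2])
  hx <- idx[hull, 1]; hy <- idx[hull, 2]
  nh <- length(hull)
  if (nh < 3) return(1)
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  min(1, area / (a + per / 2 + 1))
}

#' Classify a binary wheal mask into a morphological class
#'
#' Connected components are extracted with 8-connectivity; a component is a
#' ring when filling its holes grows the area by at least 20\%, an arc
#' fragment when it has no hole and low solidity, a filled disk when it has
#' no hole and high solidity.  Equivalent diameters are \code{2 sqrt(A/pi)}
#' (outer diameter: from the hole-filled area).  The decision cascade:
#' empty mask, uniform coverage, many small dots (fine vs ordinary by median
#' diameter), annular (large vs small by median outer diameter), broken
#' annular (arcs outnumber closed rings), circular (majority filled disks),
#' with a dots/circular fallback by median diameter.  Deterministic and
#' invariant under rotations and reflections of the mask.
#'
#' @param mask logical (or 0/1) matrix, wheal = TRUE.
#' @param mm_per_cell physical size of one grid cell in mm (274 mm domain at
#'   \code{grid_n = 512} gives 0.535).
#' @param rules thresholds from \code{\link{patternRules}}.
#' @return An object of class \code{"patternReport"}: \code{class_label},
#'   \code{n_components}, \code{component_diameters} (mm, hole-filled),
#'   \code{coverage_fraction}, \code{n_ring_components}.
#' @export
classifyMask <- function(mask, mm_per_cell, rules = patternRules()) {
  if (is.numeric(mask)) mask <- mask >= 0.5
  stopifnot(is.matrix(mask), mm_per_cell > 0)
  coverage <- mean(mask)
  report <- function(label, st = NULL, nring = 0) {
    diam <- if (is.null(st)) numeric(0) else
      2 * sqrt(st[, "filled_area"] * mm_per_cell^2 / pi)
    structure(list(class_label = label,
                   n_components = if (is.null(st)) 0L else nrow(st),
                   component_diameters = diam,
                   coverage_fraction = coverage,
                   n_ring_components = nring),
              class = "patternReport")
  }
  if (!any(mask)) return(report("none"))
  if (coverage >= rules$uniform_coverage) {
    st <- .componentStats(mask)
    return(report("uniform", st, sum(st[, "filled_area"] >=
                                       (1 + rules$ring_fill_excess) * st[, "area"])))
  }
  st <- .componentStats(mask)
  diam <- 2 * sqrt(st[, "filled_area"] * mm_per_cell^2 / pi)
  is_ring <- st[, "filled_area"] >= (1 + rules$ring_fill_excess) * st[, "area"]
  nring <- sum(is_ring)
  med <- stats::median(diam)
  if (nrow(st) >= rules$dots_min_components && med < rules$fine_diam_mm)
    return(report("fine_dots", st, nring))
  if (nrow(st) >= rules$dots_min_components && med < rules$dots_diam_mm)
    return(report("dots", st, nring))
  big <- diam >= rules$big_diam_mm
  if (any(big)) {
    ring_frac <- sum(is_ring & big) / sum(big)
    if (ring_frac >= rules$annular_fraction) {
      outer_med <- stats::median(diam[is_ring & big])
      lbl <- if (outer_med >= rules$large_outer_mm) "annular_large" else "annular_small"
      return(report(lbl, st, nring))
    }
    arcs <- sum(big & !is_ring & st[, "solidity"] < rules$arc_solidity)
    if (arcs > sum(is_ring & big)) return(report("broken_annular", st, nring))
    disks <- big & !is_ring & st[, "solidity"] >= rules$disk_solidity
    if (sum(disks) / sum(big) >= 0.5) return(report("circular", st, nring))
  }
  # all components below the ring-analysis size: dots by diameter
  if (med < rules$fine_diam_mm) return(report("fine_dots", st, nring))
  if (med < rules$dots_diam_mm) return(report("dots", st, nring))
  report("circular", st, nring)
}

#' @export
print.patternReport <- function(x, ...) {
  cat(sprintf("Pattern: %s (%d components, %d rings, coverage %.3f)\n",
              x$class_label, x$n_components, x$n_ring_components,
              x$coverage_fraction))
  if (length(x$component_diameters))
    cat(sprintf("  median equivalent diameter %.2f mm\n",
                stats::median(x$component_diameters)))
  invisible(x)
}

#' Parameter sweep: P_min and pattern class per kinetic parameter point
#'
#' For each parameter set the minimal developing stimulus is located with
#' \code{\link{findPMin}} and, where a wheal develops, a reference simulation
#' at \code{classify_factor} times the minimal stimulus is classified at its
#' final snapshot.  Individual point failures are recorded and the sweep
#' continues; when \code{out_csv} exists, completed points are skipped
#' (resumable).
#'
#' @param param_list list of \code{\link{kineticParams}} objects.
#' @param spec a \code{\link{stimulusSpec}} template.
#' @param wp a \code{\link{whealParams}} object.
#' @param cfg a \code{\link{solverConfig}} for both search and reference run.
#' @param scales a \code{\link{scaleSet}} fixing the mm-per-cell conversion.
#' @param classify_factor stimulus multiplier for the reference run.
#' @param out_csv optional CSV path for resumable results.
#' @return Data frame: parameters, \code{status}, \code{p_min},
#'   \code{class}, \code{n_components}, \code{coverage}.
#' @export
sweepRegimes <- function(param_list, spec, wp = whealParams(),
                         cfg = solverConfig(grid_n = 64, t_end = 60),
                         scales = scaleSet(), classify_factor = 1.2,
                         out_csv = NULL) {
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv))
    done <- utils::read.csv(out_csv)
  rows <- list()
  for (i in seq_along(param_list)) {
    p <- param_list[[i]]
    key <- paste(p$gamma, p$alpha0, p$alpha1, p$alpha2, p$mu, p$u_tot)
    if (!is.null(done)) {
      dk <- paste(done$gamma, done$alpha0, done$alpha1, done$alpha2,
                  done$mu, done$u_tot)
      if (key %in% dk) {
        rows[[i]] <- done[match(key, dk), , drop = FALSE]
        next
      }
    }
    row <- data.frame(gamma = p$gamma, alpha0 = p$alpha0, alpha1 = p$alpha1,
                      alpha2 = p$alpha2, mu = p$mu, u_tot = p$u_tot,
                      status = NA_character_, p_min = NA_real_,
                      class = NA_character_, n_components = NA_integer_,
                      coverage = NA_real_)
    res <- tryCatch({
      pm <- findPMin(p, spec, wp, cfg)
      row$status <- pm$status
      row$p_min <- pm$p_min
      if (pm$status == "ok") {
        sp <- spec; sp$r <- pm$r_min * classify_factor
        traj <- rdRun(p, sp, wp, cfg)
        mm_per_cell <- 10 * scales$length_cm / cfg$grid_n
        rep_ <- classifyMask(whealMask(traj), mm_per_cell)
        row$class <- rep_$class_label
        row$n_components <- rep_$n_components
        row$coverage <- rep_$coverage_fraction
      }
      row
    }, error = function(e) {
      row$status <- paste0("error: ", conditionMessage(e))
      row
    })
    rows[[i]] <- res
    if (!is.null(out_csv)) {
      all <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      utils::write.csv(all, out_csv, row.names = FALSE)
    }
  }
  do.call(rbind, rows)
}
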
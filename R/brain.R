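# Procedural gray/white brain scene. The anatomy is deliberately simple:
# an ellipsoidal cortical shell of gray matter around an interior white
# matter ellipsoid, plus four deep gray nuclei (caudate and putamen
# analogs, one pair per hemisphere). What matters for the analysis is the
# gray/white activity contrast, a cortical ribbon thin relative to the
# scanner resolution, and deep structures of varied size - not slab-level
# anatomical fidelity.

BRAIN_OUTER_SEMI_AXES <- c(70, 85, 62)    # x (left-right), y (ant-post), z
BRAIN_CORTEX_THICKNESS <- 7               # mm, gray ribbon
BRAIN_NUCLEI <- list(
  caudate_L = list(center = c(14, 18, 12), semi = c(5, 12, 7)),
  caudate_R = list(center = c(-14, 18, 12), semi = c(5, 12, 7)),
  putamen_L = list(center = c(26, 4, 2), semi = c(8, 15, 9)),
  putamen_R = list(center = c(-26, 4, 2), semi = c(8, 15, 9)))

#' Build the procedural gray/white brain scene and its VOI template
#'
#' Gray matter (cortical shell plus deep nuclei) is filled at the
#' solution concentration, white matter at `solution / gray_white_ratio`.
#' The template carries ten gray and ten white VOIs (five per hemisphere
#' per tissue) spanning large cortical patches down to small deep
#' structures; VOIs are disjoint within each tissue class and lie
#' entirely inside their tissue's label set.
#'
#' @param solution_concentration fill-solution (gray) concentration,
#'   kBq/mL (> 0).
#' @param gray_white_ratio gray-to-white activity ratio (> 1); default 4,
#'   the nominal design contrast of gray/white brain phantoms.
#' @param template_voxel_mm voxel size of the template label grid.
#' @return list with `scene` (a [scene()]) and `template` (class
#'   `brain_template`: label array 0/1/2 = outside/gray/white on a
#'   [grid_spec()], VOI definitions, and the solution concentration).
#' @export
build_brain_scene <- function(solution_concentration, gray_white_ratio = 4,
                              template_voxel_mm = 2) {
  if (!is.finite(solution_concentration) || solution_concentration <= 0)
    stop("solution_concentration must be > 0")
  if (!is.finite(gray_white_ratio) || gray_white_ratio <= 1)
    stop("gray_white_ratio must be > 1")
  white_conc <- solution_concentration / gray_white_ratio
  outer_sh <- ellipsoid_shape(c(0, 0, 0), BRAIN_OUTER_SEMI_AXES)
  inner_sh <- ellipsoid_shape(c(0, 0, 0),
                              BRAIN_OUTER_SEMI_AXES - BRAIN_CORTEX_THICKNESS)
  comps <- list(
    list(shape = outer_sh, concentration = solution_concentration, name = "cortex"),
    list(shape = inner_sh, concentration = white_conc, name = "white"))
  for (nm in names(BRAIN_NUCLEI)) {
    nucleus <- BRAIN_NUCLEI[[nm]]
    comps[[length(comps) + 1L]] <-
      list(shape = ellipsoid_shape(nucleus$center, nucleus$semi),
           concentration = solution_concentration, name = nm)
  }
  sc <- scene(comps,
              meta = list(phantom = "brain",
                          solution_concentration = solution_concentration,
                          gray_white_ratio = gray_white_ratio,
                          white_concentration = white_conc))
  template <- build_brain_template(sc, template_voxel_mm)
  list(scene = sc, template = template)
}

brain_label_at <- function(sc, pts) {
  # 0 outside, 1 gray, 2 white, by painter's order of the brain scene
  lab <- integer(nrow(pts))
  for (cp in sc$compartments) {
    inside <- shape_contains(cp$shape, pts)
    lab[inside] <- if (identical(cp$name, "white")) 2L else 1L
  }
  lab
}

build_brain_template <- function(sc, voxel_mm) {
  ext <- 2 * (BRAIN_OUTER_SEMI_AXES + 4)
  d <- as.integer(ceiling(ext / voxel_mm))
  grid <- grid_spec(rep(voxel_mm, 3), d, -d * voxel_mm / 2)
  pts <- grid_voxel_centers(grid)
  lab <- array(brain_label_at(sc, pts), dim = grid$dim)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  in_nucleus <- function(nm) {
    nucleus <- BRAIN_NUCLEI[[nm]]
    shape_contains(ellipsoid_shape(nucleus$center, nucleus$semi), pts)
  }
  vois <- list()
  add_voi <- function(name, tissue, sel) {
    sel <- sel & (as.vector(lab) == if (tissue == "gray") 1L else 2L)
    if (!any(sel)) stop(sprintf("brain template VOI '%s' is empty", name))
    vois[[name]] <<- list(name = name, tissue = tissue,
                          index = which(sel),
                          centers_mm = pts[sel, , drop = FALSE])
  }
  for (hs in c("L", "R")) {
    side <- if (hs == "L") x > 2 else x < -2
    # gray: three cortical sectors of decreasing size plus two deep nuclei
    add_voi(paste0("frontal_cortex_", hs), "gray", side & y > 45)
    add_voi(paste0("occipital_cortex_", hs), "gray", side & y < -45)
    add_voi(paste0("parietal_cortex_", hs), "gray", side & abs(y) <= 45 & z > 40)
    add_voi(paste0("caudate_", hs), "gray", in_nucleus(paste0("caudate_", hs)))
    add_voi(paste0("putamen_", hs), "gray", in_nucleus(paste0("putamen_", hs)))
    # white: sectors of varied size including one small deep sphere
    deep_ctr <- c(if (hs == "L") 22 else -22, -20, 0)
    r_deep <- sqrt((x - deep_ctr[1])^2 + (y - deep_ctr[2])^2 + (z - deep_ctr[3])^2)
    add_voi(paste0("frontal_white_", hs), "white", side & y > 20)
    add_voi(paste0("occipital_white_", hs), "white",
            side & y < -20 & r_deep > 22)
    add_voi(paste0("superior_white_", hs), "white", side & abs(y) <= 20 & z > 16)
    add_voi(paste0("deep_white_small_", hs), "white", r_deep <= 8)
    add_voi(paste0("deep_white_ring_", hs), "white",
            side & abs(y) <= 20 & z <= 16 & r_deep > 10 & r_deep <= 20)
  }
  structure(list(grid = grid, labels = lab, vois = vois,
                 solution_concentration = sc$meta$solution_concentration),
            class = "brain_template")
}

#' @export
print.brain_template <- function(x, ...) {
  cat(sprintf("<brain_template> %d VOIs on a %d x %d x %d label grid\n",
              length(x$vois), x$grid$dim[1], x$grid$dim[2], x$grid$dim[3]))
  invisible(x)
}

#' Reconstruction profiles for the brain study
#'
#' Brain-mode grids at 2 x 2 x 2 mm covering the head, with and without
#' resolution modelling (same emulation styles as
#' [iq_recon_profiles()]).
#'
#' @param fwhm baseline effective resolution, mm.
#' @param psf_iterations Richardson-Lucy iterations for the modelled
#'   profile.
#' @export
brain_recon_profiles <- function(fwhm = 7, psf_iterations = 10L) {
  ext <- 2 * (BRAIN_OUTER_SEMI_AXES + 12)
  d <- as.integer(ceiling(ext / 2))
  d <- d + d %% 2L   # keep dimensions even for clean fine-grid refinement
  g <- grid_spec(c(2, 2, 2), d, -d * 2 / 2)
  list(
    "TOF-brain" = recon_profile(g, fwhm = fwhm, label = "TOF-brain"),
    "TOF+PSF-brain" = recon_profile(g, fwhm = fwhm,
                                    psf_iterations = psf_iterations,
                                    psf_kernel_fwhm = fwhm,
                                    label = "TOF+PSF-brain"))
}
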
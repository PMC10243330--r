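# Voxelwise IVIM mapping of 4D DWI volumes and a synthetic digital brain
# phantom standing in for in-vivo acquisitions.

#' Construct a 4D diffusion-weighted volume
#'
#' @param data 4D numeric array `(x, y, z, b-index)`.
#' @param bvalues b-value per volume along the fourth dimension, s/mm^2;
#'   must contain 0.
#' @param spacing Voxel spacing, mm (length 3).
#' @param nex Optional per-b-value NEX (number-of-averages) counts.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, bvalues, spacing = c(1, 1, 1), nex = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            dim(data)[4L] == length(bvalues), 0 %in% bvalues,
            length(spacing) == 3L, all(spacing > 0))
  if (!is.null(nex)) stopifnot(length(nex) == length(bvalues), all(nex >= 1))
  structure(list(data = data, bvalues = as.numeric(bvalues),
                 spacing = as.numeric(spacing), nex = nex),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_volume> %d x %d x %d voxels, %d b-values [%s] s/mm^2\n",
              d[1], d[2], d[3], d[4], paste(x$bvalues, collapse = " ")))
  invisible(x)
}

#' Tissue labels of the phantom / mask legend
#'
#' @return Named integer vector mapping tissue names to mask labels
#'   (background = 0).
#' @export
tissue_labels <- function() {
  c(background = 0L, WM = 1L, GM = 2L, CSF = 3L, GTV = 4L)
}

#' Default tissue regimes of the digital phantom
#'
#' Synthetic tissue parameters mirroring typical in-vivo brain medians:
#' white and gray matter are low-perfused (f around 5-7%) with D near
#' 0.7e-3 mm^2/s, the tumor (GTV) carries a higher diffusion coefficient, a
#' High-perfusion-like D* and a large perfusion fraction, and CSF is nearly
#' free water. Any label can be remapped, e.g. to the Low/Medium/High
#' simulation presets of [ivim_regimes()].
#'
#' @return Named list of [perfusion_regime()] objects for WM, GM, CSF, GTV.
#' @export
phantom_regimes <- function() {
  list(WM  = perfusion_regime(0.70e-3, 9e-3, 0.055, "WM"),
       GM  = perfusion_regime(0.75e-3, 11e-3, 0.065, "GM"),
       CSF = perfusion_regime(2.0e-3, 10e-3, 0.02, "CSF"),
       GTV = perfusion_regime(1.06e-3, 60e-3, 0.21, "GTV"))
}

inside_ellipsoid <- function(cx, cy, cz, center, radii) {
  ((cx - center[1]) / radii[1])^2 + ((cy - center[2]) / radii[2])^2 +
    ((cz - center[3]) / radii[3])^2 <= 1
}

# Deterministic nested-ellipsoid label geometry in normalized [-1,1] coords:
# GM shell, WM interior, central CSF ventricles, offset GTV sphere.
phantom_geometry <- function(dim) {
  cx <- array(rep(seq(-1, 1, length.out = dim[1]), times = dim[2] * dim[3]),
              dim = dim)
  cy <- array(rep(rep(seq(-1, 1, length.out = dim[2]), each = dim[1]),
                  times = dim[3]), dim = dim)
  cz <- array(rep(seq(-1, 1, length.out = dim[3]), each = dim[1] * dim[2]),
              dim = dim)
  lab <- array(0L, dim = dim)
  lab[inside_ellipsoid(cx, cy, cz, c(0, 0, 0), c(0.95, 0.95, 0.92))] <-
    tissue_labels()[["GM"]]
  lab[inside_ellipsoid(cx, cy, cz, c(0, 0, 0), c(0.78, 0.78, 0.8))] <-
    tissue_labels()[["WM"]]
  lab[inside_ellipsoid(cx, cy, cz, c(-0.1, 0, 0), c(0.42, 0.28, 0.55))] <-
    tissue_labels()[["CSF"]]
  lab[inside_ellipsoid(cx, cy, cz, c(0.45, 0.3, 0), c(0.3, 0.32, 0.6))] <-
    tissue_labels()[["GTV"]]
  lab
}

#' Generate a synthetic digital brain phantom
#'
#' Builds a labelled 3D geometry (nested ellipsoids: gray-matter shell,
#' white-matter interior, central CSF, an offset tumor) and simulates every
#' voxel's diffusion decay from its tissue's perfusion regime, with magnitude
#' (Rician) noise and NEX averaging of independent realizations per b-value —
#' a synthetic stand-in for an in-vivo acquisition.
#'
#' @param scheme An [acquisition_scheme()].
#' @param snr Signal-to-noise ratio; `Inf` for a noiseless phantom.
#' @param dim Spatial grid size (length 3).
#' @param nex NEX count per b-value (recycled; e.g. `2`, or the clinical
#'   pattern `c(2, 2, 2, 2, 3, 3, 5)` for a 7-value scheme).
#' @param regimes Named list of [perfusion_regime()] per tissue label
#'   (names WM, GM, CSF, GTV); see [phantom_regimes()].
#' @param seed Integer seed.
#' @param S0 Baseline intensity.
#' @param spacing Voxel spacing, mm.
#' @return List with `volume` (a [dwi_volume()]) and `mask` (3D integer
#'   label array, legend [tissue_labels()]).
#' @export
generate_phantom <- function(scheme, snr = snr_from_db(50),
                             dim = c(64, 64, 12), nex = 2,
                             regimes = phantom_regimes(), seed = NULL,
                             S0 = 1000, spacing = c(1.14, 1.14, 4.8)) {
  stopifnot(inherits(scheme, "acquisition_scheme"), length(dim) == 3L)
  b <- scheme$bvalues
  nb <- length(b)
  nex <- rep_len(nex, nb)
  mask <- phantom_geometry(dim)
  vol <- array(0, dim = c(dim, nb))
  sigma <- if (is.finite(snr)) S0 / snr else 0
  with_seed(seed, {
    for (tis in names(regimes)) {
      lab <- tissue_labels()[[tis]]
      idx <- which(mask == lab)
      if (length(idx) == 0L) next
      s <- S0 * ivim_signal(b, regimes[[tis]])
      sig <- matrix(0, nb, length(idx))
      for (k in seq_len(max(nex))) {
        live <- nex >= k
        noisy <- magnitude_noise(s[live], sigma, length(idx))
        sig[live, ] <- sig[live, ] + noisy
      }
      sig <- sig / nex
      for (v in seq_len(nb)) {
        plane <- vol[, , , v]
        plane[idx] <- sig[v, ]
        vol[, , , v] <- plane
      }
    }
  })
  list(volume = dwi_volume(vol, b, spacing = spacing, nex = nex), mask = mask)
}

#' Voxelwise segmented IVIM fit of a volume
#'
#' Applies the segmented fit to every masked voxel of a 4D DWI volume.
#' Voxels labelled GTV are fitted with the wider tumor D* constraint
#' (`gtv_bounds`); background voxels are left untouched (NA in the maps).
#' Voxels with a discarded (negative) perfusion fraction carry NA in the
#' `f`/`Dstar` maps and are marked in the flag maps, so region statistics can
#' exclude them exactly as the simulations do.
#'
#' @param volume A [dwi_volume()].
#' @param mask 3D integer label array aligned to `volume` (legend
#'   [tissue_labels()]); voxels with label > 0 are fitted.
#' @param config An [fit_config()] for non-tumor tissue.
#' @param gtv_bounds D* bounds for GTV-labelled voxels, mm^2/s.
#' @return An object of class `ivim_maps`: list of 3D arrays `D`, `f`,
#'   `Dstar` and logical flag arrays `f_discarded`, `dstar_at_bound`,
#'   `converged`, plus `spacing`.
#' @export
fit_volume <- function(volume, mask, config = fit_config(),
                       gtv_bounds = c(0, 0.2)) {
  stopifnot(inherits(volume, "dwi_volume"))
  sdim <- dim(volume$data)[1:3]
  if (!identical(dim(mask), sdim)) stop("mask is not aligned to the volume")
  nb <- length(volume$bvalues)
  flat <- matrix(volume$data, ncol = nb)  # voxels x b
  idx <- which(mask > 0)
  maps <- list(D = array(NA_real_, sdim), f = array(NA_real_, sdim),
               Dstar = array(NA_real_, sdim),
               f_discarded = array(NA, sdim), dstar_at_bound = array(NA, sdim),
               converged = array(NA, sdim))
  i0 <- which(volume$bvalues == 0)[1L]
  bad <- idx[flat[idx, i0] <= 0]
  idx <- setdiff(idx, bad)

  gtv_cfg <- fit_config(threshold = config$threshold, dstar_bounds = gtv_bounds,
                        dstar_start = config$dstar_start,
                        high_inclusive = config$high_inclusive,
                        low_inclusive = config$low_inclusive,
                        include_b0 = config$include_b0,
                        atbound_tol = config$atbound_tol,
                        max_iter = config$max_iter)
  gtv <- tissue_labels()[["GTV"]]
  for (part in list(list(v = idx[mask[idx] != gtv], cfg = config),
                    list(v = idx[mask[idx] == gtv], cfg = gtv_cfg))) {
    if (length(part$v) == 0L) next
    fits <- fit_ivim_batch(t(flat[part$v, , drop = FALSE]), volume$bvalues,
                           part$cfg)
    disc <- fits$f_discarded
    maps$D[part$v] <- fits$D
    maps$f[part$v] <- ifelse(disc, NA_real_, fits$f)
    maps$Dstar[part$v] <- fits$Dstar
    maps$f_discarded[part$v] <- disc
    maps$dstar_at_bound[part$v] <- fits$dstar_at_bound
    maps$converged[part$v] <- fits$converged
  }
  maps$spacing <- volume$spacing
  structure(maps, class = "ivim_maps")
}

#' Per-region summary of IVIM parameter maps
#'
#' Median and interquartile range of each parameter within each tissue
#' label, excluding flagged (discarded or non-converged) voxels.
#'
#' @param maps An `ivim_maps` object from [fit_volume()].
#' @param mask 3D integer label array.
#' @param labels Named label legend (defaults to [tissue_labels()] without
#'   background). Empty labels are reported as NA rows.
#' @return A data.frame with columns `tissue`, `label`, `parameter`, `n`,
#'   `median`, `iqr`.
#' @export
roi_summary <- function(maps, mask, labels = tissue_labels()[-1L]) {
  stopifnot(inherits(maps, "ivim_maps"))
  do.call(rbind, lapply(names(labels), function(tis) {
    v <- which(mask == labels[[tis]])
    do.call(rbind, lapply(c("D", "f", "Dstar"), function(p) {
      x <- maps[[p]][v]
      ok <- !is.na(x) &
        !(maps$f_discarded[v] %in% TRUE) &
        (maps$converged[v] %in% TRUE)
      x <- x[ok]
      data.frame(tissue = tis, label = labels[[tis]], parameter = p,
                 n = length(x),
                 median = if (length(x)) median(x) else NA_real_,
                 iqr = if (length(x)) unname(diff(quantile(x, c(0.25, 0.75))))
                       else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Read / write DWI volumes and maps as NIfTI
#'
#' `write_dwi()` stores a [dwi_volume()] as a NIfTI-1 image plus an
#' FSL-style `.bval` file; `read_dwi()` reads them back. `write_maps()`
#' writes each parameter map of an `ivim_maps` object as a separate NIfTI
#' image (`<prefix>_D.nii.gz` etc.), with flagged voxels as NA-coded
#' sentinels.
#'
#' @param volume A [dwi_volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param bval_path b-value file path; defaults to `path` with a `.bval`
#'   extension.
#' @return `read_dwi()` returns a [dwi_volume()]; the writers return their
#'   main path invisibly.
#' @export
write_dwi <- function(volume, path, bval_path = NULL) {
  stopifnot(inherits(volume, "dwi_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(volume$spacing, 1)
  RNifti::writeNifti(img, path)
  write_bval(acquisition_scheme(volume$bvalues),
             bval_path %||% sub("\\.nii(\\.gz)?$", ".bval", path))
  invisible(path)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(path, bval_path = NULL) {
  img <- RNifti::readNifti(path)
  b <- scan(bval_path %||% sub("\\.nii(\\.gz)?$", ".bval", path),
            what = numeric(), quiet = TRUE)
  dwi_volume(array(as.numeric(img), dim = dim(img)), b,
             spacing = RNifti::pixdim(img)[1:3])
}

#' @param maps An `ivim_maps` object.
#' @param prefix Output path prefix for the per-parameter images.
#' @rdname write_dwi
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "ivim_maps"))
  for (p in c("D", "f", "Dstar")) {
    img <- RNifti::asNifti(maps[[p]])
    RNifti::pixdim(img) <- maps$spacing
    RNifti::writeNifti(img, paste0(prefix, "_", p, ".nii.gz"))
  }
  invisible(prefix)
}
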
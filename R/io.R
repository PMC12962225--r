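# Serialization: an R-native dataset container (phantom + k-space + pattern +
# metadata in one file) and NIfTI export of images, so real scanner exports
# could later be adapted to the same structure.

#' Save a simulated dataset container
#'
#' Bundles truth, field, coils, k-space (per polarity), pattern and metadata
#' (spectral model, echo times, seed) into a single file.
#'
#' @param ph a `phantom`.
#' @param kdata a `kspace_data`.
#' @param times an `echo_times`.
#' @param model a `spectral_model`.
#' @param path output file path (`.rds`).
#' @export
save_wfs_dataset <- function(ph, kdata, times, model, path) {
  obj <- list(truth = ph$truth, field = ph$field, coils = ph$coils,
              ghost_phase = ph$ghost_phase,
              kspace = list(pos = kdata$y[, , , , 1L],
                            neg = kdata$y[, , , , 2L]),
              pattern = kdata$pattern,
              meta = list(model = unclass(model), times = unclass(times),
                          seed = ph$cfg$seed, sigma = kdata$sigma,
                          cfg = unclass(ph$cfg)))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a dataset container saved by [save_wfs_dataset()]
#' @param path file path.
#' @return list with `phantom` fields, `kdata` (a `kspace_data`), `times`,
#'   `model`.
#' @export
load_wfs_dataset <- function(path) {
  obj <- readRDS(path)
  d <- dim(obj$kspace$pos)
  y <- array(0i, c(d, 2L))
  y[, , , , 1L] <- obj$kspace$pos
  y[, , , , 2L] <- obj$kspace$neg
  times <- structure(obj$meta$times, class = "echo_times")
  model <- structure(obj$meta$model, class = "spectral_model")
  kdata <- structure(list(y = y, pattern = obj$pattern, times = times,
                          sigma = obj$meta$sigma), class = "kspace_data")
  list(truth = obj$truth, field = obj$field, coils = obj$coils,
       ghost_phase = obj$ghost_phase, kdata = kdata, times = times,
       model = model, meta = obj$meta)
}

#' Write a single 2D image as NIfTI (1 mm isotropic)
#' @param img real or complex matrix (magnitude written if complex).
#' @param path output `.nii` path.
#' @export
write_nifti_image <- function(img, path) {
  if (is.complex(img)) img <- Mod(img)
  vol <- array(img, c(dim(img), 1L))
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(1, 1, 1)), path)
  invisible(path)
}

#' Write the three species images as NIfTI volumes
#' @param rho a `species_images`.
#' @param prefix path prefix; `_water/_fat/_silicone.nii` are appended.
#' @export
write_species_nifti <- function(rho, prefix) {
  write_nifti_image(rho$w, paste0(prefix, "_water.nii"))
  write_nifti_image(rho$f, paste0(prefix, "_fat.nii"))
  write_nifti_image(rho$s, paste0(prefix, "_silicone.nii"))
  invisible(prefix)
}

# grayscale PNG montage of named magnitude images
write_montage_png <- function(imgs, path) {
  n <- length(imgs)
  ncol_ <- ceiling(sqrt(n)); nrow_ <- ceiling(n / ncol_)
  grDevices::png(path, width = 220 * ncol_, height = 220 * nrow_)
  op <- graphics::par(mfrow = c(nrow_, ncol_), mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  for (nm in names(imgs)) {
    m <- imgs[[nm]]
    graphics::image(t(m[nrow(m):1, ]), axes = FALSE, col = grDevices::gray.colors(256),
                    main = nm)
  }
  invisible(path)
}
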
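#' 3D fiber image container
#'
#' A `fiber_image` bundles a 3D intensity array with its physical voxel
#' spacing (micrometre, in `(z, y, x)` axis order), an origin, and provenance
#' metadata. The processing history is append-only: every standardization
#' step records itself via [fi_record()], which is what the pipeline-order
#' checks and the JSONL labbook rely on.
#'
#' @param voxels 3D numeric array indexed `(z, y, x)`; the fiber main axis is
#'   `y` once the image is standardized.
#' @param spacing numeric length-3, micrometre per voxel along `(z, y, x)`.
#' @param origin physical coordinate of voxel `(1,1,1)` in micrometre.
#' @param sample_id,study_id identifiers carried into the cohort manifest.
#' @param mask optional foreground mask (same dimensions, logical).
#' @return an object of class `fiber_image`.
#' @export
fiber_image <- function(voxels, spacing, origin = c(0, 0, 0),
                        sample_id = NA_character_, study_id = NA_character_,
                        mask = NULL) {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3, all(spacing > 0))
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         mask = mask,
         meta = list(sample_id = sample_id, study_id = study_id,
                     history = list())),
    class = "fiber_image")
}

#' @export
print.fiber_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<fiber_image %s> %d x %d x %d voxels (z,y,x) @ %.3g/%.3g/%.3g um\n",
              x$meta$sample_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (length(x$meta$history))
    cat("  history:", paste(vapply(x$meta$history, `[[`, "", "step"),
                            collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.fiber_image <- function(x) dim(x$voxels)

# Append a processing-history entry (append-only by construction).
fi_record <- function(img, step, params = list()) {
  img$meta$history <- c(img$meta$history, list(list(step = step, params = params)))
  img
}

#' Processing-history step names of an image
#' @param img a [fiber_image()].
#' @return character vector in application order.
#' @export
fi_steps <- function(img) vapply(img$meta$history, `[[`, "", "step")

fi_mask <- function(img) {
  if (!is.null(img$mask)) return(img$mask)
  img$voxels > 0
}

#' Read and write fiber volumes
#'
#' Volumes are stored as multi-page grayscale TIFF (one page per z-slice,
#' 32-bit float) with the voxel spacing in the image description, or as NIfTI
#' with spacing in the header. Both round-trip the `(z, y, x)` array layout.
#'
#' @param img a [fiber_image()].
#' @param path output file; extension `.tif`/`.tiff` or `.nii`/`.nii.gz`.
#' @return `write_fiber_image()` returns `path` invisibly; `read_fiber_image()`
#'   returns a [fiber_image()].
#' @export
write_fiber_image <- function(img, path) {
  d <- dim(img$voxels)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    # NIfTI stores x fastest; reorder (z,y,x) -> (x,y,z)
    arr <- aperm(img$voxels, c(3, 2, 1))
    nif <- RNifti::asNifti(arr)
    RNifti::pixdim(nif) <- rev(img$spacing)
    RNifti::writeNifti(nif, path)
  } else {
    # TIFF pages store [0,1] samples; the voxel rescale and spacing travel
    # in a JSON sidecar next to the stack
    rng <- range(img$voxels)
    scl <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(d[1]), function(z)
      matrix((img$voxels[z, , ] - rng[1]) / scl, d[2], d[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(spacing_um = img$spacing, offset = rng[1],
                              scale = scl),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_fiber_image
#' @param spacing fallback spacing when the file carries none.
#' @export
read_fiber_image <- function(path, spacing = c(0.5, 0.5, 0.5)) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    nif <- RNifti::readNifti(path)
    sp <- rev(RNifti::pixdim(nif)[1:3])
    arr <- aperm(as.array(nif), c(3, 2, 1))
    return(fiber_image(arr, sp))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  offset <- 0; scl <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    sp <- as.numeric(meta$spacing_um)
    if (length(sp) == 3 && all(is.finite(sp)) && all(sp > 0)) spacing <- sp
    if (!is.null(meta$offset)) offset <- meta$offset
    if (!is.null(meta$scale)) scl <- meta$scale
  }
  d2 <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * scl + offset
  fiber_image(arr, spacing)
}

#' Append one entry to a JSONL labbook
#'
#' Every pipeline stage logs what it did (step names, parameters, checksums)
#' as one JSON object per line, so a run can be audited or resumed.
#'
#' @param path labbook file (created on first use).
#' @param entry a named list; serialized with `jsonlite`.
#' @return `path`, invisibly.
#' @export
labbook_append <- function(path, entry) {
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA, null = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' @rdname labbook_append
#' @export
labbook_read <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = TRUE)
}

array_checksum <- function(arr) {
  v <- as.vector(arr)
  sprintf("%.6e", sum(v) + sum(v * seq_along(v) %% 97))
}
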
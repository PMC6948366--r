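#' Write a simulated session to disk
#'
#' Emits an FSL-style session directory: `dwi.nii.gz`, `bvals`, `bvecs`
#' (FSL dialect), `labels.nii.gz` (when labels are supplied),
#' `masks/{brain,gm,wm,air,artifact}.nii.gz` and `truth.json` with the
#' ground-truth parameters.
#'
#' @param dwi a [dwi_volume()].
#' @param dir output directory (created if needed).
#' @param labels optional integer label volume.
#' @param artifact optional artifact mask.
#' @param truth optional list serialised to `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_session <- function(dwi, dir, labels = NULL, artifact = NULL,
                          truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  wr <- function(x, path, dtype = "float") {
    attr(x, "pixdim") <- c(dwi$voxsize, 1)[seq_len(length(dim(x)))]
    RNifti::writeNifti(RNifti::asNifti(x, datatype = dtype), path)
  }
  wr(dwi$signal, file.path(dir, "dwi.nii.gz"))
  write_bvalbvec(dwi$gtab, file.path(dir, "bvals"), file.path(dir, "bvecs"))
  for (m in names(dwi$masks))
    if (!is.null(dwi$masks[[m]]))
      wr(array(as.integer(dwi$masks[[m]]), dim(dwi$masks[[m]])),
         file.path(dir, "masks", paste0(m, ".nii.gz")), dtype = "int16")
  if (!is.null(labels))
    wr(array(as.integer(labels), dim(labels)), file.path(dir, "labels.nii.gz"),
       dtype = "int16")
  if (!is.null(artifact))
    wr(array(as.integer(artifact), dim(artifact)),
       file.path(dir, "masks", "artifact.nii.gz"), dtype = "int16")
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory.
#' @param session session tag for the returned volume.
#' @return A [dwi_volume()] (plus `labels`/`artifact` attributes when
#'   present on disk).
#' @export
read_session <- function(dir, session = "pre") {
  sig <- RNifti::readNifti(file.path(dir, "dwi.nii.gz"))
  gtab <- read_bvalbvec(file.path(dir, "bvals"), file.path(dir, "bvecs"))
  voxsize <- RNifti::pixdim(sig)[1:3]
  masks <- list()
  for (m in c("brain", "gm", "wm", "air")) {
    p <- file.path(dir, "masks", paste0(m, ".nii.gz"))
    if (file.exists(p)) masks[[m]] <- array(RNifti::readNifti(p) > 0,
                                            dim(sig)[1:3])
  }
  dwi <- dwi_volume(array(as.numeric(sig), dim(sig)), gtab, voxsize, session,
                    masks)
  labp <- file.path(dir, "labels.nii.gz")
  if (file.exists(labp))
    attr(dwi, "labels") <- array(as.integer(RNifti::readNifti(labp)),
                                 dim(sig)[1:3])
  artp <- file.path(dir, "masks", "artifact.nii.gz")
  if (file.exists(artp))
    attr(dwi, "artifact") <- array(RNifti::readNifti(artp) > 0, dim(sig)[1:3])
  dwi
}

#' Write a scalar map as NIfTI
#'
#' Float32 image named `{session}_{fa|md|rd}.nii.gz` in `dir`.
#'
#' @param map a `scalar_map`.
#' @param dir output directory.
#' @return The file path, invisibly.
#' @export
write_scalar_map <- function(map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- map$values
  vals[is.na(vals)] <- 0
  attr(vals, "pixdim") <- map$voxsize
  img <- RNifti::asNifti(vals, datatype = "float")
  path <- file.path(dir, sprintf("%s_%s.nii.gz", map$session %||% "session",
                                 tolower(map$kind)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
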
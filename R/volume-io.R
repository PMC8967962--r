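#' Construct a MaskVolume from an array
#'
#' Any nonzero value in `voxels` is mapped to 1, so masks stored as
#' 0/255 or logical arrays are accepted. Spacing must be strictly
#' positive in all three axes.
#'
#' @param voxels 3-D numeric, integer or logical array.
#' @param spacing numeric length-3, mm per voxel along (x, y, z).
#' @param sourcePath optional provenance label.
#' @param metadata optional list of annotations.
#' @return A [MaskVolume-class] object.
#' @examples
#' arr <- array(0, dim = c(4, 4, 2)); arr[2:3, 2:3, ] <- 255
#' m <- MaskVolume(arr, spacing = c(1, 1, 5))
#' foregroundCount(m)  # 8
#' @export
MaskVolume <- function(voxels, spacing = c(1, 1, 1), sourcePath = "",
                       metadata = list()) {
    if (is.null(dim(voxels)) || length(dim(voxels)) != 3L)
        stop("'voxels' must be a 3-D array, got ",
             paste(dim(voxels), collapse = "x"))
    v <- array(as.integer(voxels != 0), dim = dim(voxels))
    methods::new("MaskVolume", voxels = v, spacing = as.numeric(spacing),
                 sourcePath = as.character(sourcePath), metadata = metadata)
}

#' @rdname maskVoxels
#' @export
setMethod("maskVoxels", "MaskVolume", function(x) x@voxels)

#' @rdname maskVoxels
#' @export
setMethod("voxelSpacing", "MaskVolume", function(x) x@spacing)

#' @rdname maskVoxels
#' @export
setMethod("sourcePath", "MaskVolume", function(x) x@sourcePath)

#' @rdname maskVoxels
#' @export
setMethod("maskMetadata", "MaskVolume", function(x) x@metadata)

#' @rdname maskVoxels
#' @export
setMethod("foregroundCount", "MaskVolume", function(x) sum(x@voxels))

#' @describeIn MaskVolume-class dimensions of the voxel lattice.
#' @param x a MaskVolume.
#' @export
setMethod("dim", "MaskVolume", function(x) dim(x@voxels))

setMethod("show", "MaskVolume", function(object) {
    d <- dim(object@voxels)
    cat("MaskVolume:", paste(d, collapse = " x "), "voxels,",
        "spacing", paste(format(object@spacing), collapse = " x "), "mm\n")
    cat("  foreground:", sum(object@voxels), "voxels\n")
    if (nzchar(object@sourcePath))
        cat("  source:", object@sourcePath, "\n")
})

# mm coordinates of given voxel indices (n x 3, 1-based): (idx-1)*spacing
voxelToMM <- function(idx, spacing) {
    sweep(idx - 1, 2L, spacing, "*")
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Loads a `.nii`/`.nii.gz` volume, binarizes it (any nonzero value
#' becomes 1) and takes the voxel spacing from the header. When the file
#' carries a usable orientation (qform/sform), axes are reordered to the
#' canonical RAS frame so that x = left-right, y = anterior-posterior,
#' z = cranial-caudal; headerless synthetic volumes are taken as already
#' canonical.
#'
#' @param path path to an existing NIfTI-1 file.
#' @return A [MaskVolume-class] with `sourcePath` set to `path`.
#' @seealso [writeMask()]
#' @export
readMask <- function(path) {
    if (!file.exists(path))
        stop("mask file does not exist: ", path)
    img <- RNifti::readNifti(path)
    if (length(dim(img)) > 3L)
        stop("expected a 3-D volume, got ", length(dim(img)),
             " dimensions in ", path)
    ori <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
    if (!is.na(ori) && nzchar(ori) && ori != "RAS") {
        img <- tryCatch({
            RNifti::orientation(img) <- "RAS"
            img
        }, warning = function(w) img, error = function(e) img)
    }
    arr <- as.array(img)
    # degenerate trailing singleton axes are collapsed by the reader;
    # restore the 3-D lattice contract
    if (length(dim(arr)) < 3L)
        dim(arr) <- c(dim(arr), rep(1L, 3L - length(dim(arr))))
    sp <- RNifti::pixdim(img)
    sp <- c(sp, rep(1, 3))[seq_len(3)]
    if (any(!is.finite(sp)) || any(sp <= 0))
        stop("invalid voxel spacing in header of ", path, ": ",
             paste(format(sp), collapse = ", "))
    MaskVolume(arr, spacing = abs(sp), sourcePath = path)
}

#' Write a binary mask to a NIfTI-1 file
#'
#' The voxel spacing is encoded in the header pixdim; `.nii.gz` paths
#' are gzip-compressed. `readMask(writeMask(m, path))` reproduces the
#' lattice and spacing exactly.
#'
#' @param mask a [MaskVolume-class].
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
    stopifnot(methods::is(mask, "MaskVolume"))
    if (!dir.exists(dirname(path)))
        stop("parent directory does not exist: ", dirname(path))
    img <- RNifti::asNifti(mask@voxels)
    RNifti::pixdim(img) <- mask@spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
    invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a UTF-8 CSV with a header row and columns `patient_id`,
#' `predicted_mask_path`, `ground_truth_mask_path` and optionally
#' `fold`. Relative mask paths are resolved against the directory
#' containing the manifest, so cohorts are relocatable.
#'
#' @param path path to the CSV file.
#' @return data.frame with the manifest rows in file order; mask paths
#'   resolved, `fold` integer or `NA`.
#' @seealso [makeCohort()] which writes manifests in this layout.
#' @export
readManifest <- function(path) {
    if (!file.exists(path))
        stop("manifest file does not exist: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("patient_id", "predicted_mask_path",
                  "ground_truth_mask_path")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("manifest is missing required column(s): ",
             paste(missing, collapse = ", "))
    dup <- df$patient_id[duplicated(df$patient_id)]
    if (length(dup))
        stop("duplicate patient_id in manifest: ",
             paste(unique(dup), collapse = ", "))
    same <- df$predicted_mask_path == df$ground_truth_mask_path
    if (any(same))
        stop("predicted and ground-truth paths identical for: ",
             paste(df$patient_id[same], collapse = ", "))
    if (is.null(df$fold)) df$fold <- NA_integer_
    df$fold <- as.integer(df$fold)
    base <- dirname(normalizePath(path))
    resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                  file.path(base, p))
    df$predicted_mask_path <- resolve(df$predicted_mask_path)
    df$ground_truth_mask_path <- resolve(df$ground_truth_mask_path)
    df
}
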
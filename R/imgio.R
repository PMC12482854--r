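#' Construct an image volume
#'
#' A 3-D scalar field (PET uptake or anatomical intensity) together with its
#' 4x4 voxel-to-world affine. Voxel indices are 0-based; world coordinates are
#' RAS millimetres; all geometry goes through the affine, never through an
#' assumed axis order.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 invertible voxel-to-world matrix (mm, RAS).
#' @param space `"native"` or `"template"`.
#' @return object of class `image_volume` with fields `data`, `affine`,
#'   `space`.
#' @export
image_volume <- function(data, affine, space = c("native", "template")) {
  space <- match.arg(space)
  check_volume_geometry(data, affine)
  structure(list(data = data, affine = affine, space = space),
            class = "image_volume")
}

check_volume_geometry <- function(data, affine) {
  if (length(dim(data)) != 3L) stopf("expected 3-D volume, got %d dimensions",
                                     length(dim(data)))
  if (!is.matrix(affine) || any(dim(affine) != 4L))
    stopf("affine must be a 4x4 matrix")
  if (any(!is.finite(affine))) stopf("affine contains non-finite values")
  if (abs(det(affine)) < 1e-12) stopf("affine is not invertible")
  invisible(TRUE)
}

#' Construct a labelled (parcellation) volume
#'
#' @param labels 3-D array of non-negative integer labels; 0 is background.
#' @param affine 4x4 voxel-to-world matrix.
#' @param dictionary a [label_dictionary()]; every nonzero label present in
#'   `labels` must appear in it.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, affine, dictionary) {
  check_volume_geometry(labels, affine)
  if (any(labels < 0)) stopf("labels must be non-negative")
  if (any(labels != round(labels))) stopf("labels must be integers")
  dictionary <- as_label_dictionary(dictionary)
  present <- setdiff(unique(as.integer(labels)), 0L)
  unknown <- setdiff(present, dictionary$id)
  if (length(unknown))
    stopf("labels not in dictionary: %s", paste(sort(unknown), collapse = ", "))
  structure(list(labels = labels, affine = affine, dictionary = dictionary),
            class = "label_volume")
}

#' Label dictionary
#'
#' Maps integer structure ids to names and tissue classes (GM/WM/CSF).
#' The bundled default follows the Neuromorphometrics protocol naming with 132
#' structures of which 122 are grey matter; structure ids are package-assigned
#' (the protocol's own id table is not redistributed here) and the file can be
#' replaced by any CSV with columns `id,name,tissue`.
#'
#' @param entries data frame with columns `id` (positive integer, unique),
#'   `name` (character), `tissue` (one of GM, WM, CSF).
#' @return data frame of class `label_dictionary`.
#' @export
label_dictionary <- function(entries) {
  req <- c("id", "name", "tissue")
  if (!all(req %in% names(entries)))
    stopf("dictionary needs columns: %s", paste(req, collapse = ", "))
  entries <- as.data.frame(entries)[req]
  entries$id <- as.integer(entries$id)
  entries$name <- as.character(entries$name)
  entries$tissue <- as.character(entries$tissue)
  if (any(is.na(entries$id)) || any(entries$id <= 0L))
    stopf("dictionary ids must be positive integers")
  dup <- entries$id[duplicated(entries$id)]
  if (length(dup)) stopf("duplicate dictionary id(s): %s",
                         paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(entries$tissue), c("GM", "WM", "CSF"))
  if (length(bad)) stopf("unknown tissue class(es): %s",
                         paste(bad, collapse = ", "))
  class(entries) <- c("label_dictionary", "data.frame")
  entries
}

as_label_dictionary <- function(x) {
  if (inherits(x, "label_dictionary")) x else label_dictionary(x)
}

#' Load a label dictionary from CSV (or the bundled default)
#'
#' @param path CSV/TSV file with columns `id,name,tissue`; `NULL` loads the
#'   bundled 132-structure default.
#' @return a [label_dictionary()].
#' @export
load_label_dictionary <- function(path = NULL) {
  path <- path %||% pkg_extdata("label_dictionary.csv")
  if (!file.exists(path)) stopf("dictionary file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  label_dictionary(utils::read.table(path, header = TRUE, sep = sep,
                                     stringsAsFactors = FALSE))
}

#' Grey-matter ids of a dictionary
#' @param dictionary a [label_dictionary()].
#' @return integer vector of GM structure ids.
#' @export
gm_ids <- function(dictionary) {
  dictionary <- as_label_dictionary(dictionary)
  dictionary$id[dictionary$tissue == "GM"]
}

#' Sampling-grid specification
#'
#' @param shape integer triple of grid dimensions.
#' @param affine 4x4 voxel-to-world matrix of the grid.
#' @return object of class `space_spec`.
#' @export
space_spec <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (any(!is.finite(affine)) || abs(det(affine)) < 1e-12)
    stopf("space_spec affine must be finite and invertible")
  structure(list(shape = shape, affine = affine), class = "space_spec")
}

#' MNI-like template grid: 181 x 217 x 181 voxels at 1 mm isotropic
#' @return a [space_spec()].
#' @export
template_space <- function() {
  aff <- diag(4)
  aff[1:3, 4] <- c(-90, -126, -72)
  space_spec(c(181L, 217L, 181L), aff)
}

#' Small centred isotropic grid used by the phantom generator
#' @param shape grid dimensions (default 64^3).
#' @param voxel_mm isotropic voxel size in mm (default 2).
#' @return a [space_spec()].
#' @export
phantom_space <- function(shape = c(64L, 64L, 64L), voxel_mm = 2) {
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -(shape - 1) * voxel_mm / 2
  space_spec(shape, aff)
}

#' Voxel volume (mm^3) implied by an affine
#' @param affine 4x4 voxel-to-world matrix.
#' @return scalar mm^3.
#' @export
voxel_volume <- function(affine) abs(det(affine[1:3, 1:3]))

voxel_size <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

as_space_spec <- function(x) {
  if (inherits(x, "space_spec")) return(x)
  if (inherits(x, "image_volume")) return(space_spec(dim(x$data), x$affine))
  if (inherits(x, "label_volume")) return(space_spec(dim(x$labels), x$affine))
  stopf("cannot interpret object of class '%s' as a sampling grid",
        paste(class(x), collapse = "/"))
}

#' Read a 3-D NIfTI-1 volume
#'
#' Header scaling slope/intercept are applied by the reader. The affine is
#' taken from the sform/qform (voxel-to-world, RAS).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param space space tag to attach, `"native"` or `"template"`.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, space = "native") {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("expected 3-D volume, got %d-D in %s", length(d), path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (any(!is.finite(aff)))
    stopf("non-finite affine in %s", path)
  data <- array(as.numeric(img), dim = d)
  image_volume(data, aff, space = space)
}

#' Write a volume as NIfTI-1
#'
#' Scalar volumes are stored as 32-bit float by default (exact for data already
#' at float32 precision; pass `datatype = "double"` for bit-exact storage of
#' arbitrary doubles); label volumes as unsigned 16-bit integers. The affine is
#' written to both sform and qform; NIfTI-1 stores it in single precision, so
#' it round-trips to about 1e-6.
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype storage type override (e.g. `"float"`, `"double"`,
#'   `"uint16"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  if (inherits(vol, "label_volume")) {
    data <- vol$labels
    affine <- vol$affine
    datatype <- datatype %||% "uint16"
  } else if (inherits(vol, "image_volume")) {
    data <- vol$data
    affine <- vol$affine
    datatype <- datatype %||% "float"
  } else stopf("write_volume expects an image_volume or label_volume")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxel_size(affine)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a labelled volume
#'
#' @param path NIfTI file of integer labels.
#' @param dictionary a [label_dictionary()] covering the labels present.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path, dictionary = load_label_dictionary()) {
  v <- read_volume(path)
  lab <- v$data
  if (any(lab != round(lab)))
    stopf("label volume %s contains non-integer values", path)
  label_volume(array(as.integer(round(lab)), dim(lab)), v$affine, dictionary)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %s space, voxels %s mm\n",
              paste(dim(x$data), collapse = "x"), x$space,
              paste(signif(voxel_size(x$affine), 4), collapse = "x")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, %d labels present, dictionary of %d\n",
              paste(dim(x$labels), collapse = "x"),
              length(setdiff(unique(as.integer(x$labels)), 0L)),
              nrow(x$dictionary)))
  invisible(x)
}
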
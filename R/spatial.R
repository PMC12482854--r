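#' Rigid (6-parameter) world-to-world transform
#'
#' Rotation angles are in degrees, applied in the order Rz %*% Ry %*% Rx about
#' `center` (world mm), followed by the translation:
#' `T(x) = R (x - c) + c + t`. The homogeneous matrix is regenerated from the
#' parameters, so the two representations always agree.
#'
#' @param rotations length-3 rotation angles (degrees, about x, y, z).
#' @param translations length-3 translation (mm).
#' @param center world-space rotation centre (mm).
#' @return object of class `rigid_transform` (also `affine_transform`) with
#'   fields `rotations`, `translations`, `center`, `matrix`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotations) == 3, length(translations) == 3,
            length(center) == 3)
  if (any(!is.finite(c(rotations, translations, center))))
    stopf("rigid transform parameters must be finite")
  m <- rigid_matrix(rotations, translations, center)
  structure(list(rotations = as.numeric(rotations),
                 translations = as.numeric(translations),
                 center = as.numeric(center), matrix = m),
            class = c("rigid_transform", "affine_transform"))
}

rotation_matrix3 <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

rigid_matrix <- function(rotations, translations, center) {
  R <- rotation_matrix3(rotations)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center + translations - R %*% center
  m
}

#' General affine world-to-world transform
#' @param matrix invertible 4x4 homogeneous matrix.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  if (!is.matrix(matrix) || any(dim(matrix) != 4L))
    stopf("affine transform must be a 4x4 matrix")
  if (any(!is.finite(matrix)) || abs(det(matrix)) < 1e-12)
    stopf("affine transform must be finite and invertible")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' Identity transform
#' @return an [affine_transform()].
#' @export
identity_transform <- function() affine_transform(diag(4))

#' Compose two transforms into a single map
#'
#' Returns the transform equivalent to applying `first`, then `second`
#' (`second(first(x))`), so a PET-to-anatomy rigid map composed with an
#' anatomy-to-template affine gives a direct PET-to-template map usable with a
#' single interpolation.
#'
#' @param first,second transforms ([rigid_transform()] or
#'   [affine_transform()]).
#' @return an [affine_transform()].
#' @export
compose_transforms <- function(first, second) {
  affine_transform(transform_matrix(second) %*% transform_matrix(first))
}

transform_matrix <- function(x) {
  if (inherits(x, "affine_transform")) return(x$matrix)
  if (is.matrix(x) && all(dim(x) == 4L)) return(x)
  stopf("not a transform: class '%s'", paste(class(x), collapse = "/"))
}

#' Invert a transform
#' @param transform a transform.
#' @return an [affine_transform()].
#' @export
invert_transform <- function(transform) {
  affine_transform(solve(transform_matrix(transform)))
}

#' Apply a transform to world-space points
#' @param transform a transform.
#' @param points 3 x N matrix (or length-3 vector) of world coordinates.
#' @return transformed coordinates, same shape.
#' @export
apply_transform <- function(transform, points) {
  m <- transform_matrix(transform)
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, 3, 1)
  out <- m[1:3, 1:3] %*% points + m[1:3, 4]
  if (vec) as.vector(out) else out
}

# trilinear sample of array at continuous 0-based voxel coords (3 x N);
# coords outside the grid return `fill`. Returns list(values, inside).
trilinear_sample <- function(src, vox, fill = 0) {
  d <- dim(src)
  i0 <- floor(vox[1, ]); j0 <- floor(vox[2, ]); k0 <- floor(vox[3, ])
  fi <- vox[1, ] - i0; fj <- vox[2, ] - j0; fk <- vox[3, ] - k0
  ok <- i0 >= 0 & j0 >= 0 & k0 >= 0 &
    i0 <= d[1] - 2L & j0 <= d[2] - 2L & k0 <= d[3] - 2L
  # points exactly on the upper face are still inside
  hi <- vox[1, ] == d[1] - 1L | vox[2, ] == d[2] - 1L | vox[3, ] == d[3] - 1L
  if (any(hi & !ok)) {
    fix <- hi & !ok &
      vox[1, ] >= 0 & vox[1, ] <= d[1] - 1L &
      vox[2, ] >= 0 & vox[2, ] <= d[2] - 1L &
      vox[3, ] >= 0 & vox[3, ] <= d[3] - 1L
    i0[fix] <- pmin(i0[fix], d[1] - 2L)
    j0[fix] <- pmin(j0[fix], d[2] - 2L)
    k0[fix] <- pmin(k0[fix], d[3] - 2L)
    fi[fix] <- vox[1, fix] - i0[fix]
    fj[fix] <- vox[2, fix] - j0[fix]
    fk[fix] <- vox[3, fix] - k0[fix]
    ok <- ok | fix
  }
  out <- rep(fill, ncol(vox))
  if (any(ok)) {
    i <- i0[ok]; j <- j0[ok]; k <- k0[ok]
    a <- fi[ok]; b <- fj[ok]; c <- fk[ok]
    base <- 1 + i + d[1] * (j + d[2] * k)
    o2 <- d[1]; o3 <- d[1] * d[2]
    v000 <- src[base];           v100 <- src[base + 1]
    v010 <- src[base + o2];      v110 <- src[base + o2 + 1]
    v001 <- src[base + o3];      v101 <- src[base + o3 + 1]
    v011 <- src[base + o3 + o2]; v111 <- src[base + o3 + o2 + 1]
    out[ok] <- (1 - c) * ((1 - b) * ((1 - a) * v000 + a * v100) +
                          b * ((1 - a) * v010 + a * v110)) +
               c * ((1 - b) * ((1 - a) * v001 + a * v101) +
                    b * ((1 - a) * v011 + a * v111))
  }
  list(values = out, inside = ok)
}

nearest_sample <- function(src, vox, fill = 0) {
  d <- dim(src)
  i <- round(vox[1, ]); j <- round(vox[2, ]); k <- round(vox[3, ])
  ok <- i >= 0 & j >= 0 & k >= 0 & i <= d[1] - 1L & j <= d[2] - 1L &
    k <= d[3] - 1L
  out <- rep(fill, ncol(vox))
  if (any(ok))
    out[ok] <- src[1 + i[ok] + d[1] * (j[ok] + d[2] * k[ok])]
  list(values = out, inside = ok)
}

#' Resample a volume onto a target grid with a single interpolation
#'
#' The transform maps the volume's world frame to the target's world frame.
#' Chained registrations should be composed with [compose_transforms()] and
#' applied here once: each interpolation pass blurs, so the whole geometric
#' chain is collapsed into one pass. Voxels mapping outside the source get 0.
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param transform world-to-world transform (default identity).
#' @param target a [space_spec()], [image_volume()] or [label_volume()]
#'   defining the output grid.
#' @param interpolation `"trilinear"` or `"nearest"`. Label volumes are always
#'   resampled with nearest-neighbour so no new label values can appear.
#' @return resampled volume of the same class as `vol`, on the target grid.
#' @export
resample_once <- function(vol, transform = identity_transform(), target,
                          interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  tgt <- as_space_spec(target)
  is_label <- inherits(vol, "label_volume")
  if (is_label && interpolation != "nearest")
    stopf("label volumes must be resampled with nearest-neighbour interpolation")
  src_aff <- if (is_label) vol$affine else vol$affine
  src <- if (is_label) vol$labels else vol$data
  # target voxel -> target world -> source world -> source voxel
  M <- solve(src_aff) %*% solve(transform_matrix(transform)) %*% tgt$affine
  vox <- M[1:3, 1:3] %*% voxel_grid(tgt$shape) + M[1:3, 4]
  smp <- if (interpolation == "trilinear") trilinear_sample(src, vox)
         else nearest_sample(src, vox)
  out <- array(smp$values, tgt$shape)
  if (is_label)
    label_volume(array(as.integer(out), tgt$shape), tgt$affine, vol$dictionary)
  else
    image_volume(out, tgt$affine, space = vol$space)
}

#' Write / read a transform as plain text with a JSON sidecar
#'
#' The 4x4 matrix is written one row per line; rigid parameters (if any) go to
#' `<path>.json`.
#'
#' @param transform a transform.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  m <- transform_matrix(transform)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  side <- list(type = class(transform)[1])
  if (inherits(transform, "rigid_transform")) {
    side$rotations_deg <- transform$rotations
    side$translations_mm <- transform$translations
    side$center_mm <- transform$center
  }
  write_json_file(side, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stopf("transform file not found: %s", path)
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != 4 || any(lengths(rows) != 4))
    stopf("transform file %s is not a 4x4 matrix", path)
  m <- do.call(rbind, lapply(rows, as.numeric))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    s <- read_json(side)
    if (identical(s$type, "rigid_transform"))
      return(rigid_transform(s$rotations_deg, s$translations_mm, s$center_mm))
  }
  affine_transform(m)
}

#' @export
print.affine_transform <- function(x, ...) {
  if (inherits(x, "rigid_transform"))
    cat(sprintf("<rigid_transform> rot (deg): %s  trans (mm): %s\n",
                paste(signif(x$rotations, 4), collapse = ", "),
                paste(signif(x$translations, 4), collapse = ", ")))
  else cat("<affine_transform>\n")
  print(signif(x$matrix, 6))
  invisible(x)
}
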
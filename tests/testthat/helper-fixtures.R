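# shared fixtures, built in code at test time

# minimal dictionary: two GM structures, one WM, one CSF
tiny_dictionary <- function() {
  label_dictionary(data.frame(
    id = c(1L, 2L, 3L, 4L),
    name = c("Region A", "Region B", "White", "Fluid"),
    tissue = c("GM", "GM", "WM", "CSF")))
}

# small labelled cube: two GM slabs, a WM slab and empty background
tiny_labels <- function(shape = c(10L, 10L, 10L), voxel = 2) {
  lab <- array(0L, shape)
  lab[2:5, 2:9, 2:9] <- 1L
  lab[6:9, 2:9, 2:9] <- 2L
  lab[2:9, 2:9, 1] <- 3L
  sp <- phantom_space(shape, voxel)
  label_volume(lab, sp$affine, tiny_dictionary())
}

uniform_pet <- function(labels, values) {
  ids <- as.integer(names(values))
  lut <- numeric(max(c(ids, as.integer(labels$labels))) + 1L)
  lut[ids + 1L] <- values
  image_volume(array(lut[as.integer(labels$labels) + 1L], dim(labels$labels)),
               labels$affine)
}

# smooth random gaussian-blob field: analytic function of world coordinates,
# plus its sampling on a grid — the analytic form serves as ground truth for
# interpolation error comparisons
analytic_phantom <- function(seed = 1, shape = c(48L, 48L, 48L), voxel = 2,
                             n_blobs = 25) {
  sp <- phantom_space(shape, voxel)
  set.seed(seed)
  centres <- matrix(runif(3 * n_blobs, -30, 30), 3)
  widths <- runif(n_blobs, 6, 14)
  amps <- runif(n_blobs, 0.5, 2)
  field <- function(world) { # world: 3 x N
    out <- numeric(ncol(world))
    for (b in seq_len(n_blobs))
      out <- out + amps[b] * exp(-colSums((world - centres[, b])^2) /
                                   (2 * widths[b]^2))
    out
  }
  g <- sp$affine[1:3, 1:3] %*%
    rbind(rep(0:(shape[1] - 1), shape[2] * shape[3]),
          rep(rep(0:(shape[2] - 1), each = shape[1]), shape[3]),
          rep(0:(shape[3] - 1), each = shape[1] * shape[2])) + sp$affine[1:3, 4]
  list(vol = image_volume(array(field(g), shape), sp$affine),
       field = field, grid_world = g, space = sp)
}

smooth_phantom <- function(...) analytic_phantom(...)$vol

# brute-force per-voxel region statistics (independent oracle)
brute_region_stats <- function(pet, labels) {
  dict <- labels$dictionary
  res <- lapply(dict$id, function(id) {
    vals <- pet$data[labels$labels == id]
    keep <- vals[is.finite(vals) & vals >= 0]
    c(mean = if (length(keep)) sum(keep) / length(keep) else NA_real_,
      voxels = length(vals), valid = length(keep))
  })
  do.call(rbind, res)
}

full_dictionary <- load_label_dictionary()
full_masks <- load_composite_masks(full_dictionary)
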
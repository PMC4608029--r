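# Rasterization of closed curves into tube-density volumes, noise/blur
# corruption, and population generation.

#' Specification of a synthetic minicircle population
#'
#' Imaging and sampling parameters shared by all records of a generated
#' population. The box must contain every curve with a 180 A margin so the
#' radius-of-gyration mask (which extends 180 A from the traced path) never
#' truncates; [generate_population()] enforces this.
#'
#' @param counts Named integer vector of per-class record counts; names are
#'   shape classes (see [shape_spec()]).
#' @param voxel_size Sampling in A/voxel. Default 4.52, the tomogram pixel
#'   size of the source data.
#' @param box_edge Box edge in voxels, or `NULL` to size automatically.
#' @param tube_radius Gaussian tube sigma in A (duplex radius). Default 10.
#' @param noise_sd Additive Gaussian noise sd relative to the unit peak tube
#'   density. Default 0.2.
#' @param blur_sigma Isotropic Gaussian blur sigma in A applied before
#'   noise. Default 8.
#' @param margin Minimum clearance (A) between the curve and the box faces.
#'   Default 180, the radius-of-gyration mask extent.
#' @param seed Integer master seed; each record's seed derives from it.
#' @param contour_length,n_points Passed to [shape_spec()] for every record.
#' @return A `population_spec` list.
#' @export
population_spec <- function(counts,
                            voxel_size = 4.52,
                            box_edge = NULL,
                            tube_radius = 10,
                            noise_sd = 0.2,
                            blur_sigma = 8,
                            margin = 180,
                            seed = 1L,
                            contour_length = 336 * 3.4,
                            n_points = 200) {
  if (is.null(names(counts)) || !all(names(counts) %in% SHAPE_CLASSES)) {
    stop("`counts` must be named by shape classes: ",
         paste(SHAPE_CLASSES, collapse = ", "))
  }
  counts <- vapply(counts, as.integer, integer(1))
  if (any(counts < 0)) stop("counts must be >= 0")
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (noise_sd < 0 || blur_sigma < 0) stop("noise_sd and blur_sigma must be >= 0")
  structure(list(counts = counts, voxel_size = voxel_size,
                 box_edge = box_edge, tube_radius = tube_radius,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 margin = margin, seed = as.integer(seed),
                 contour_length = contour_length, n_points = n_points),
            class = "population_spec")
}

#' Rasterize a closed curve into a tube-density volume
#'
#' Density at a voxel is a Gaussian function of its distance `d` to the
#' curve axis: `exp(-d^2 / (2 * tube_radius^2))`, peaking at exactly 1 on
#' the axis and set to exactly 0 beyond `3 * tube_radius`.
#'
#' @inheritParams as_curve_matrix
#' @param voxel_size Voxel edge in A.
#' @param tube_radius Tube Gaussian sigma in A.
#' @param margin Clearance (A) between curve and box faces; used when the
#'   box is sized automatically.
#' @param box_edge Optional box edge in voxels (cubic). An error names the
#'   required size if the curve plus margin does not fit.
#' @param origin Optional origin override (A, length 3).
#' @return A [density_volume].
#' @export
rasterize <- function(curve, voxel_size = 4.52, tube_radius = 10,
                      margin = 30, box_edge = NULL, origin = NULL) {
  m <- as_curve_matrix(curve)
  lo <- apply(m, 2, min) - margin
  hi <- apply(m, 2, max) + margin
  need <- as.integer(ceiling(max(hi - lo) / voxel_size)) + 1L
  if (is.null(box_edge)) box_edge <- need
  box_edge <- as.integer(box_edge)
  if (box_edge < need) {
    stop(sprintf(paste0("curve plus %.0f A margin does not fit in a %d-voxel ",
                        "box; at least %d voxels required"),
                 margin, box_edge, need))
  }
  if (is.null(origin)) {
    ctr <- (lo + hi) / 2
    origin <- ctr - (box_edge - 1) * voxel_size / 2
  }
  dim3 <- rep(box_edge, 3L)
  d <- cpp_dist_field(dim3, voxel_size, origin, m, cutoff = 3 * tube_radius)
  dens <- ifelse(is.finite(d) & d <= 3 * tube_radius,
                 exp(-d^2 / (2 * tube_radius^2)), 0)
  density_volume(array(dens, dim3), voxel_size = voxel_size, origin = origin)
}

#' Corrupt a volume with blur and additive Gaussian noise
#'
#' Output is the Gaussian-blurred input plus i.i.d. Gaussian noise,
#' deterministic for a fixed seed. With `noise_sd = 0` and
#' `blur_sigma = 0` the input is returned unchanged.
#'
#' @param volume A [density_volume].
#' @param noise_sd Noise standard deviation (same units as the density;
#'   relative to the unit tube peak for [rasterize()] output).
#' @param blur_sigma Blur sigma in Angstroms.
#' @param seed Integer seed for the noise draw.
#' @return A [density_volume].
#' @export
corrupt <- function(volume, noise_sd = 0.2, blur_sigma = 8, seed = 1L) {
  stopifnot(inherits(volume, "density_volume"))
  if (noise_sd < 0 || blur_sigma < 0) stop("noise_sd and blur_sigma must be >= 0")
  if (noise_sd == 0 && blur_sigma == 0) return(volume)
  dat <- volume$data
  if (blur_sigma > 0) {
    b <- cpp_gaussian_blur(as.numeric(dat), dim(dat),
                           blur_sigma / volume$voxel_size)
    dat <- array(b, dim(dat))
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(dat), sd = noise_sd))
    dat <- dat + array(noise, dim(dat))
  }
  density_volume(dat, volume$voxel_size, volume$origin)
}

#' Generate a labelled population of phantom minicircle volumes
#'
#' Generates `sum(counts)` ground-truth curves (seeded deterministically
#' from the population seed), rasterizes each into a tube-density volume
#' and applies blur + noise. The returned tibble is its own manifest: any
#' record can be regenerated from its row.
#'
#' @param pop A [population_spec()].
#' @return A tibble with one row per record: `record_id`, `shape_class`,
#'   `seed`, generation parameters, and list-columns `curve` (ground-truth
#'   tibble) and `volume` ([density_volume]).
#' @export
generate_population <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  counts <- pop$counts[pop$counts > 0]
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("empty population: all counts are zero")
  }
  labels <- rep(names(counts), counts)
  n <- length(labels)
  seeds <- (as.double(pop$seed) * 10007 + seq_len(n) * 271) %% 2147483647
  seeds <- as.integer(seeds)

  # fixed cubic box holding the largest curve extent plus margin: the most
  # extended class is the rod (length ~ contour/2)
  if (is.null(pop$box_edge)) {
    extent <- pop$contour_length / 2 + 2 * DNA_TUBE_RADIUS
    edge <- as.integer(ceiling((extent + 2 * pop$margin) / pop$voxel_size)) + 1L
  } else {
    edge <- as.integer(pop$box_edge)
  }

  rows <- purrr::map(seq_len(n), function(i) {
    spec <- shape_spec(labels[i], contour_length = pop$contour_length,
                       n_points = pop$n_points)
    curve <- make_curve(spec, seed = seeds[i])
    vol <- rasterize(curve, voxel_size = pop$voxel_size,
                     tube_radius = pop$tube_radius, margin = pop$margin,
                     box_edge = edge)
    vol <- corrupt(vol, noise_sd = pop$noise_sd, blur_sigma = pop$blur_sigma,
                   seed = seeds[i] + 1L)
    tibble::tibble(record_id = sprintf("rec%04d", i),
                   shape_class = labels[i], seed = seeds[i],
                   contour_length = pop$contour_length,
                   voxel_size = pop$voxel_size,
                   tube_radius = pop$tube_radius,
                   noise_sd = pop$noise_sd, blur_sigma = pop$blur_sigma,
                   box_edge = edge,
                   curve = list(curve), volume = list(vol))
  })
  dplyr::bind_rows(rows)
}
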
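#' Specification for a synthetic fluorescence field
#'
#' Describes one simulated smooth-muscle-cell field of view with three
#' channels (mitochondrial marker, diffuse cytoplasm marker, nuclear
#' counterstain).  Cells sit on a jittered grid; each cell's cytoplasm is a
#' disk clipped to the field and to the Voronoi territory of its nucleus, so
#' cells abut without overlapping.  Mitochondria are grown per cell as
#' correlated random-walk filaments anchored perinuclearly and dilated to
#' `filament_width_px`; the `fragmentation` parameter removes evenly spaced
#' interior stretches of each filament, sweeping the morphology from a fused,
#' reticular network (0) to a granular, fissioned one (1).
#'
#' Defaults describe a 256 x 256 px confocal-like field of nine cells with a
#' moderate signal-to-noise ratio (foreground 100 over background 10, additive
#' Gaussian noise SD 5) and a point-spread blur of 0.8 px.  At a nominal
#' 0.14 um/px this corresponds to ~0.5 um-wide mitochondria imaged near the
#' diffraction limit.
#'
#' @param width_px,height_px Field dimensions in pixels.
#' @param n_cells Number of cells (nuclei) in the field.
#' @param nucleus_radius_px,cytoplasm_radius_px Nuclear and cytoplasmic disk
#'   radii; the cytoplasm radius must exceed the nucleus radius.
#' @param n_filaments_per_cell Number of mitochondrial filaments per cell.
#' @param filament_length_px Random-walk length of each filament, in steps of
#'   about one pixel.
#' @param filament_width_px Diameter to which filament skeletons are dilated.
#' @param fragmentation In \[0, 1\]: 0 keeps filaments intact (fused network),
#'   1 chops every filament into short granules.
#' @param psf_sigma_px Gaussian point-spread-function SD; 0 disables blurring.
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @param background Background intensity level.
#' @param foreground Foreground amplitude added on top of the background for
#'   in-focus structures.
#' @param seed Integer seed; the same spec always renders bit-identical output.
#' @return An object of class `synthetic_image_spec`.
#' @export
image_spec <- function(width_px = 256, height_px = 256, n_cells = 9,
                       nucleus_radius_px = 7, cytoplasm_radius_px = 34,
                       n_filaments_per_cell = 5, filament_length_px = 45,
                       filament_width_px = 3.5, fragmentation = 0.3,
                       psf_sigma_px = 0.8, noise_sd = 5, background = 10,
                       foreground = 100, seed = 1) {
  check_number(width_px, "width_px", lower = 8, integer = TRUE)
  check_number(height_px, "height_px", lower = 8, integer = TRUE)
  check_number(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_number(nucleus_radius_px, "nucleus_radius_px", lower = 0,
               strict_lower = TRUE)
  check_number(cytoplasm_radius_px, "cytoplasm_radius_px", lower = 0,
               strict_lower = TRUE)
  if (cytoplasm_radius_px <= nucleus_radius_px)
    abort_field("cytoplasm_radius_px", "must exceed nucleus_radius_px")
  check_number(n_filaments_per_cell, "n_filaments_per_cell", lower = 1,
               integer = TRUE)
  check_number(filament_length_px, "filament_length_px", lower = 2)
  check_number(filament_width_px, "filament_width_px", lower = 0,
               strict_lower = TRUE)
  check_number(fragmentation, "fragmentation", lower = 0, upper = 1)
  check_number(psf_sigma_px, "psf_sigma_px", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(background, "background", lower = 0)
  check_number(foreground, "foreground", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_cells = as.integer(n_cells),
                 nucleus_radius_px = nucleus_radius_px,
                 cytoplasm_radius_px = cytoplasm_radius_px,
                 n_filaments_per_cell = as.integer(n_filaments_per_cell),
                 filament_length_px = filament_length_px,
                 filament_width_px = filament_width_px,
                 fragmentation = fragmentation,
                 psf_sigma_px = psf_sigma_px,
                 noise_sd = noise_sd,
                 background = background,
                 foreground = foreground,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# near-square grid layout for n cells: c(rows, cols)
grid_dims <- function(n) {
  rows <- floor(sqrt(n))
  c(rows, ceiling(n / rows))
}

# integer offsets of a disk of radius r (includes the origin)
disk_offsets <- function(r) {
  d <- ceiling(r)
  g <- expand.grid(di = -d:d, dj = -d:d)
  g[g$di^2 + g$dj^2 <= r^2 + 1e-9, , drop = FALSE]
}

# separable Gaussian blur with replicate padding
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_rows <- function(m) {
    nr <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(nr, r), , drop = FALSE])
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[j:(j + nr - 1L), , drop = FALSE]
    out
  }
  t(blur_rows(t(blur_rows(x))))
}

# step indices of one filament retained after fragmentation breaks
fragment_keep <- function(n_steps, fragmentation, filament_width_px) {
  keep <- rep(TRUE, n_steps)
  gap <- ceiling(filament_width_px) + 3L  # wide enough that dilation cannot rejoin
  max_breaks <- floor(n_steps / (gap + 4L))
  # stochastic rounding keeps the expected break count (and hence the
  # expected granule size) continuous in the fragmentation parameter
  n_exact <- fragmentation * max_breaks
  n_breaks <- floor(n_exact) + (runif(1) < n_exact - floor(n_exact))
  if (n_breaks < 1L) return(keep)
  centers <- round(seq(0, n_steps, length.out = n_breaks + 2L))
  centers <- centers[2L:(n_breaks + 1L)]
  lo <- floor((gap - 1L) / 2)
  hi <- gap - 1L - lo
  for (ce in centers) {
    idx <- max(1L, ce - lo):min(n_steps, ce + hi)
    keep[idx] <- FALSE
  }
  keep
}

#' Generate one synthetic fluorescence field with ground truth
#'
#' Renders the three intensity channels from the ground-truth masks (filament
#' skeletons dilated to width, Gaussian-blurred, noise added) and returns both
#' the image and the truth.  Truth statistics are computed on the truth masks
#' with the same component/edge definitions used by [measure_field()], so a
#' perfect segmentation reproduces them exactly.
#'
#' @param spec A [image_spec()].
#' @return A list with elements `image` (a [field_image]) and `truth`, a list
#'   of class `field_ground_truth` holding `mito_mask`, `cyto_mask`,
#'   `nuclei_mask`, `true_component_count`, `true_edge_length`,
#'   `true_network_area`, `true_cytoplasm_area` and `true_n_nuclei`.
#' @export
generate_field <- function(spec) {
  if (!inherits(spec, "synthetic_image_spec"))
    abort_field("spec", "must be created by image_spec()")
  withr::with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  nr <- spec$height_px
  nc <- spec$width_px
  g <- grid_dims(spec$n_cells)
  sp_r <- nr / g[1L]
  sp_c <- nc / g[2L]
  jit <- 0.15 * min(sp_r, sp_c)

  cy <- cx <- numeric(spec$n_cells)
  for (k in seq_len(spec$n_cells)) {
    gi <- (k - 1L) %/% g[2L] + 1L
    gj <- (k - 1L) %% g[2L] + 1L
    cy[k] <- (gi - 0.5) * sp_r + runif(1, -jit, jit)
    cx[k] <- (gj - 0.5) * sp_c + runif(1, -jit, jit)
  }

  I <- matrix(rep(seq_len(nr), nc), nr)
  J <- matrix(rep(seq_len(nc), each = nr), nr)
  best_d2 <- matrix(Inf, nr, nc)
  vor <- matrix(0L, nr, nc)
  for (k in seq_len(spec$n_cells)) {
    d2 <- (I - cy[k])^2 + (J - cx[k])^2
    upd <- d2 < best_d2
    vor[upd] <- k
    best_d2[upd] <- d2[upd]
  }
  nuclei_mask <- best_d2 <= spec$nucleus_radius_px^2
  cyto_mask <- best_d2 <= spec$cytoplasm_radius_px^2

  # grow filaments as correlated random walks from perinuclear anchors,
  # bouncing back toward the nucleus at the cytoplasm boundary
  r_lim2 <- (spec$cytoplasm_radius_px - 1)^2
  n_steps <- max(2L, round(spec$filament_length_px))
  px_y <- integer(0)
  px_x <- integer(0)
  inside <- function(k, y, x) {
    yi <- round(y); xi <- round(x)
    yi >= 1 && yi <= nr && xi >= 1 && xi <= nc &&
      vor[yi, xi] == k && (y - cy[k])^2 + (x - cx[k])^2 <= r_lim2
  }
  for (k in seq_len(spec$n_cells)) {
    for (f in seq_len(spec$n_filaments_per_cell)) {
      phi <- runif(1, 0, 2 * pi)
      r0 <- spec$nucleus_radius_px + 1.5
      py <- cy[k] + r0 * sin(phi)
      px <- cx[k] + r0 * cos(phi)
      theta <- phi + rnorm(1, 0, 0.4)
      ys <- xs <- numeric(n_steps)
      for (s in seq_len(n_steps)) {
        theta <- theta + rnorm(1, 0, 0.25)
        ny_ <- py + sin(theta)
        nx_ <- px + cos(theta)
        if (!inside(k, ny_, nx_)) {
          theta <- atan2(cy[k] - py, cx[k] - px) + rnorm(1, 0, 0.3)
          ny_ <- py + sin(theta)
          nx_ <- px + cos(theta)
          if (!inside(k, ny_, nx_)) {  # cornered: stall one step in place
            ny_ <- py
            nx_ <- px
          }
        }
        py <- ny_
        px <- nx_
        ys[s] <- py
        xs[s] <- px
      }
      keep <- fragment_keep(n_steps, spec$fragmentation,
                            spec$filament_width_px)
      px_y <- c(px_y, round(ys[keep]))
      px_x <- c(px_x, round(xs[keep]))
    }
  }

  mito_mask <- matrix(FALSE, nr, nc)
  offs <- disk_offsets(spec$filament_width_px / 2)
  for (o in seq_len(nrow(offs))) {
    yy <- px_y + offs$di[o]
    xx <- px_x + offs$dj[o]
    ok <- yy >= 1L & yy <= nr & xx >= 1L & xx <= nc
    mito_mask[cbind(yy[ok], xx[ok])] <- TRUE
  }
  mito_mask <- mito_mask & cyto_mask

  truth <- structure(list(
    mito_mask = mito_mask,
    cyto_mask = cyto_mask,
    nuclei_mask = nuclei_mask,
    true_component_count = count_components(mito_mask, 8),
    true_edge_length = boundary_edge_length(mito_mask),
    true_network_area = as.integer(sum(mito_mask)),
    true_cytoplasm_area = as.integer(sum(cyto_mask)),
    true_n_nuclei = count_components(nuclei_mask, 8)
  ), class = "field_ground_truth")

  render <- function(mask, amplitude) {
    ch <- spec$background + amplitude * mask
    if (spec$psf_sigma_px > 0) ch <- gauss_blur(ch, spec$psf_sigma_px)
    if (spec$noise_sd > 0)
      ch <- ch + matrix(rnorm(length(ch), 0, spec$noise_sd), nr, nc)
    pmax(ch, 0)
  }
  img <- field_image(render(mito_mask, spec$foreground),
                     render(cyto_mask, 0.6 * spec$foreground),
                     render(nuclei_mask, spec$foreground))
  list(image = img, truth = truth)
}

#' Generate a group of independent synthetic fields
#'
#' Emulates repeated imaging of fields of view within one experimental group:
#' each field is generated with a per-field seed derived deterministically
#' from the master seed.
#'
#' @param spec A [image_spec()]; its own `seed` entry is ignored.
#' @param n_fields Number of fields (>= 1).
#' @param seed Master integer seed.
#' @return A list of `n_fields` results of [generate_field()].
#' @export
generate_group <- function(spec, n_fields, seed) {
  if (!inherits(spec, "synthetic_image_spec"))
    abort_field("spec", "must be created by image_spec()")
  check_number(n_fields, "n_fields", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  derived <- withr::with_seed(seed, sample.int(2147483646L, n_fields))
  lapply(derived, function(s) {
    sp <- spec
    sp$seed <- as.integer(s)
    generate_field(sp)
  })
}
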
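#' Specification for synthetic measurement fixtures
#'
#' Bundles everything the fixture generators need: the circumferential grid,
#' ground-truth domain geometry, the noise level, the prescribed flow field
#' for speckle movies, and the speckle rendering parameters. A given seed
#' fixes every generated output bit-exactly.
#'
#' @param seed RNG seed.
#' @param circumference circumference of the straightened cortex, um.
#' @param n grid points along the circumference.
#' @param domains data frame (or list coercible to one) with columns
#'   `center`, `width`, `amplitude`: ground-truth domains. `width` is the
#'   full width at half maximum; edges fall off over a half-cosine shoulder.
#' @param noise additive Gaussian noise standard deviation.
#' @param shoulder shoulder (edge ramp) width, um; default 6% of the domain
#'   width.
#' @param flow list describing the prescribed velocity field for movies:
#'   `type` one of `"none"`, `"uniform"`, `"sinusoidal"`, `"bipolar"`, plus
#'   `u` (amplitude, px/frame) and optionally `wavelength` (px).
#' @param speckle list with `density` (particles/px^2), `sigma`
#'   (point-spread width, px), `size` (c(ny, nx) image size), `amplitude`.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, circumference = 120, n = 512,
                           domains = NULL, noise = 0, shoulder = NULL,
                           flow = list(type = "none", u = 0),
                           speckle = list(
                             density = 0.02, sigma = 1.2,
                             size = c(128, 128), amplitude = 1
                           )) {
  domains <- if (is.null(domains)) {
    tibble::tibble(center = numeric(0), width = numeric(0), amplitude = numeric(0))
  } else {
    tibble::as_tibble(domains)
  }
  stopifnot(noise >= 0, n > 0, circumference > 0)
  if (sum(domains$width) >= circumference) {
    stop("domain widths must sum to less than the circumference", call. = FALSE)
  }
  structure(
    list(
      seed = seed, circumference = circumference, n = n, domains = domains,
      noise = noise, shoulder = shoulder, flow = flow, speckle = speckle
    ),
    class = "synthetic_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) {
    assign(".Random.seed", old, globalenv())
  } else if (exists(".Random.seed", globalenv())) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic circumferential intensity trace with known domains
#'
#' Sums smooth top-hat domains (half-cosine shoulders, periodic wrap) and
#' adds seeded Gaussian noise. The returned object carries the ground truth
#' so recovery tests can score themselves.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_profile`: `profile` (tibble with
#'   `position`, `intensity`), `truth` (the domain table), `spec`.
#' @examples
#' sp <- synthetic_spec(domains = data.frame(center = 30, width = 25, amplitude = 10))
#' make_profile(sp)
#' @export
make_profile <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$circumference
  x <- seq(0, L, length.out = spec$n + 1)[seq_len(spec$n)]
  intensity <- rep(0, spec$n)
  d <- spec$domains
  for (i in seq_len(nrow(d))) {
    sw <- spec$shoulder %||% (0.06 * d$width[i])
    intensity <- intensity +
      d$amplitude[i] * tophat_smooth(circ_dist(x, d$center[i], L), d$width[i], sw)
  }
  if (spec$noise > 0) {
    intensity <- intensity + with_seed(spec$seed, stats::rnorm(spec$n, 0, spec$noise))
  }
  structure(
    list(
      profile = tibble::tibble(position = x, intensity = intensity),
      truth = d, spec = spec
    ),
    class = "synthetic_profile"
  )
}

# smooth top-hat: 1 inside, half-cosine shoulder of width sw centred on the
# half-maximum radius w/2, so w is the full width at half maximum
tophat_smooth <- function(dist, w, sw) {
  if (sw <= 0) {
    return(as.numeric(dist <= w / 2))
  }
  r0 <- w / 2 - sw / 2
  r1 <- w / 2 + sw / 2
  out <- numeric(length(dist))
  out[dist <= r0] <- 1
  ramp <- dist > r0 & dist < r1
  out[ramp] <- 0.5 * (1 + cos(pi * (dist[ramp] - r0) / sw))
  out
}

# prescribed x-velocity (px/frame) at pixel column positions xpx in [0, nx)
flow_u <- function(flow, xpx, nx) {
  type <- flow$type %||% "none"
  u <- flow$u %||% 0
  switch(type,
    none = rep(0, length(xpx)),
    uniform = rep(u, length(xpx)),
    sinusoidal = u * sin(2 * pi * xpx / (flow$wavelength %||% nx)),
    bipolar = u * sin(2 * pi * xpx / nx),
    stop("unknown flow type: ", type, call. = FALSE)
  )
}

#' Synthetic speckle movie advected by a prescribed velocity field
#'
#' Places particles uniformly at random, renders them as Gaussian spots,
#' and advects them frame to frame by the prescribed x-velocity field with
#' periodic wrap. Emulates a cortical myosin speckle movie with a known
#' displacement field, the benchmark input for the PIV operators.
#'
#' @param spec a [synthetic_spec()] (fields `flow`, `speckle`, `seed`).
#' @param n_frames number of frames (>= 2).
#' @param photon_noise if `TRUE`, replaces intensities by Poisson counts
#'   (scaled by 50 photons per intensity unit).
#' @return A list of class `speckle_movie`: `frames` (list of matrices),
#'   `truth_u` (prescribed x-displacement per pixel column, px/frame),
#'   `spec`.
#' @export
make_speckle_movie <- function(spec, n_frames = 2, photon_noise = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"), n_frames >= 2)
  sk <- spec$speckle
  ny <- sk$size[1]
  nx <- sk$size[2]
  if (is.null(sk$density) || sk$density <= 0) {
    stop("particle density must be positive", call. = FALSE)
  }
  n_part <- max(1, round(sk$density * nx * ny))
  pos <- with_seed(spec$seed, cbind(
    x = runif(n_part, 0, nx),
    y = runif(n_part, 0, ny)
  ))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- render_speckles(pos, nx, ny, sk$sigma, sk$amplitude %||% 1)
    if (photon_noise) {
      img <- with_seed(spec$seed + f, matrix(
        stats::rpois(length(img), img * 50) / 50, ny, nx
      ))
    }
    frames[[f]] <- img
    u <- flow_u(spec$flow, pos[, "x"], nx)
    pos[, "x"] <- (pos[, "x"] + u) %% nx
  }
  structure(
    list(
      frames = frames,
      truth_u = flow_u(spec$flow, seq_len(nx) - 1, nx),
      spec = spec
    ),
    class = "speckle_movie"
  )
}

# draw Gaussian spots at continuous positions onto a pixel grid
render_speckles <- function(pos, nx, ny, sigma, amplitude) {
  img <- matrix(0, ny, nx)
  r <- ceiling(4 * sigma)
  off <- (-r):r
  for (p in seq_len(nrow(pos))) {
    xc <- pos[p, "x"]
    yc <- pos[p, "y"]
    xi <- round(xc) + off
    yi <- round(yc) + off
    gx <- exp(-((xi - xc)^2) / (2 * sigma^2))
    gy <- exp(-((yi - yc)^2) / (2 * sigma^2))
    patch <- amplitude * outer(gy, gx)
    xi <- (xi %% nx) + 1
    yi <- (yi %% ny) + 1
    img[yi, xi] <- img[yi, xi] + patch
  }
  img
}

#' Write / read a synthetic profile with its ground-truth sidecar
#'
#' The trace goes to a two-column tab-separated table and the ground truth
#' (domain table plus generator settings) to a YAML sidecar named
#' `<path>.truth.yml`, so fixtures round-trip losslessly through text files.
#'
#' @param x a `synthetic_profile`.
#' @param path output path for the TSV table.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns
#'   a list with `profile` and `truth`.
#' @export
write_profile <- function(x, path) {
  stopifnot(inherits(x, "synthetic_profile"))
  utils::write.table(x$profile, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  truth <- list(
    domains = lapply(seq_len(nrow(x$truth)), function(i) as.list(x$truth[i, ])),
    seed = x$spec$seed, circumference = x$spec$circumference,
    n = x$spec$n, noise = x$spec$noise
  )
  yaml::write_yaml(truth, paste0(path, ".truth.yml"), precision = 15)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  profile <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  truth_raw <- yaml::read_yaml(paste0(path, ".truth.yml"))
  truth <- if (length(truth_raw$domains)) {
    dplyr::bind_rows(lapply(truth_raw$domains, tibble::as_tibble))
  } else {
    tibble::tibble(center = numeric(0), width = numeric(0), amplitude = numeric(0))
  }
  list(
    profile = profile, truth = truth,
    meta = truth_raw[setdiff(names(truth_raw), "domains")]
  )
}
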
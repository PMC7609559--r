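#' Velocity-encoded measurement plane
#'
#' A cross-sectional velocity measurement as produced by velocity-encoded
#' MRI: three velocity components (two in-plane, one through-plane) sampled
#' on a regular 2-D grid, with a circular lumen mask.
#'
#' @param x,y grid coordinate vectors, m (pixel centres).
#' @param vx,vy in-plane velocity components, m/s; matrices of dimension
#'   `length(x)` by `length(y)`.
#' @param vz through-plane velocity component, m/s; same dimension.
#' @param mask logical matrix marking lumen pixels.
#' @param center lumen centre `c(x, y)`, m.
#' @param radius lumen radius, m.
#' @param id optional plane identifier.
#' @return An object of class `velocity_plane`.
#' @export
velocity_plane <- function(x, y, vx, vy, vz, mask, center, radius,
                           id = NA_character_) {
  dims <- c(length(x), length(y))
  for (nm in c("vx", "vy", "vz", "mask")) {
    m <- get(nm)
    if (!is.matrix(m) || !all(dim(m) == dims)) {
      stop(nm, " must be a ", dims[1], " x ", dims[2], " matrix",
           call. = FALSE)
    }
  }
  if (!any(mask)) stop("lumen mask is empty", call. = FALSE)
  if (!is.finite(radius) || radius <= 0) {
    stop("lumen radius must be > 0", call. = FALSE)
  }
  structure(list(x = x, y = y, vx = vx, vy = vy, vz = vz, mask = mask,
                 center = center, radius = radius, id = id),
            class = "velocity_plane")
}

#' @export
print.velocity_plane <- function(x, ...) {
  cat(sprintf(
    "<velocity_plane> %d x %d grid, lumen radius %.1f mm, flow %.1f ml/s\n",
    length(x$x), length(x$y), 1e3 * x$radius, plane_flow(x)))
  invisible(x)
}

#' Integrated through-plane flow of a plane
#'
#' Discrete quadrature of the through-plane velocity over the lumen mask.
#'
#' @param plane a [velocity_plane()].
#' @return flow, ml/s.
#' @export
plane_flow <- function(plane) {
  stopifnot(inherits(plane, "velocity_plane"))
  da <- min(diff(plane$x)) * min(diff(plane$y))
  sum(plane$vz[plane$mask]) * da / 1e-6
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# wrap velocities into (-venc, venc], emulating phase aliasing
wrap_venc <- function(x, venc) {
  x - 2 * venc * ceiling((x - venc) / (2 * venc))
}

#' Synthesize a velocity-encoded measurement plane
#'
#' Builds a synthetic cross-sectional velocity measurement with known ground
#' truth. The through-plane component is a blunted jet
#' \eqn{u(\rho') = U (1 - (\rho'/R)^k)} centred at a displacement `d * R`
#' from the lumen centre (\eqn{\rho'} is the distance from the displaced
#' centre, the profile clipped to zero where the jet shape would be
#' negative inside the lumen), scaled so that the noise-free discrete
#' integral equals `q_mls` exactly. The in-plane component is a solid-body
#' swirl about the lumen centre with edge speed `s`. Independent Gaussian
#' noise of standard deviation `noise_sd` is added per component inside the
#' mask, and, when a velocity-encoding limit `venc` is given, every
#' component is wrapped into `(-venc, venc]` as in phase-contrast aliasing.
#'
#' @param radius lumen radius, m.
#' @param q_mls target through-plane flow, ml/s (> 0).
#' @param profile list with `k` (bluntness exponent, >= 2), `d` (jet
#'   displacement as a fraction of the radius, in `[0, 1)`), and either `s`
#'   (swirl edge speed, m/s) or `sfd` (a target secondary-flow degree from
#'   which `s` is computed on the noise-free field).
#' @param noise_sd per-component Gaussian noise, m/s.
#' @param venc velocity-encoding limit, m/s, or `NULL` to disable aliasing.
#' @param seed RNG seed for the noise draws.
#' @param n grid resolution (n x n over the lumen bounding square).
#' @return A [velocity_plane()] with an attached `ground_truth` list
#'   (`d`, `s`, `k`, `q_mls`, `sfd`).
#' @export
synthesize_plane <- function(radius, q_mls,
                             profile = list(k = 2, d = 0, s = 0),
                             noise_sd = 0, venc = NULL, seed = 1L, n = 64L) {
  if (!is.finite(q_mls) || q_mls <= 0) {
    stop("q_mls must be > 0", call. = FALSE)
  }
  k <- profile$k %||% 2
  d <- profile$d %||% 0
  if (d < 0 || d >= 1) stop("displacement d must lie in [0, 1)", call. = FALSE)
  if (k < 2) stop("bluntness exponent k must be >= 2", call. = FALSE)
  stopifnot(noise_sd >= 0, n >= 8)

  half <- radius * (1 + 1 / n)
  x <- seq(-half, half, length.out = n)
  y <- x
  gx <- outer(x, rep(1, n)); gy <- outer(rep(1, n), y)
  mask <- gx^2 + gy^2 <= radius^2
  if (!any(mask)) stop("lumen mask is empty", call. = FALSE)
  da <- diff(x)[1] * diff(y)[1]

  rho_d <- sqrt((gx - d * radius)^2 + gy^2)
  shape <- pmax(1 - (rho_d / radius)^k, 0)   # first arg keeps the dim
  shape[!mask] <- 0
  scale <- (q_mls * 1e-6) / (sum(shape) * da)
  vz <- shape * scale

  rho <- sqrt(gx^2 + gy^2)
  s <- profile$s %||% 0
  if (!is.null(profile$sfd)) {
    # edge speed giving exactly the requested SFD on the noise-free field
    mean_inplane_unit <- mean((rho / radius)[mask])
    s <- profile$sfd * mean(vz[mask]) / mean_inplane_unit
  }
  vx <- -s * gy / radius
  vy <- s * gx / radius
  vx[!mask] <- 0; vy[!mask] <- 0
  sfd_true <- if (mean(vz[mask]) > 0) {
    mean(sqrt(vx^2 + vy^2)[mask]) / mean(vz[mask])
  } else NA_real_

  if (noise_sd > 0) {
    npx <- sum(mask)
    noise <- with_seed(seed, matrix(rnorm(3 * npx, sd = noise_sd), ncol = 3))
    vx[mask] <- vx[mask] + noise[, 1]
    vy[mask] <- vy[mask] + noise[, 2]
    vz[mask] <- vz[mask] + noise[, 3]
  }
  if (!is.null(venc)) {
    stopifnot(venc > 0)
    vx[mask] <- wrap_venc(vx[mask], venc)
    vy[mask] <- wrap_venc(vy[mask], venc)
    vz[mask] <- wrap_venc(vz[mask], venc)
  }
  pl <- velocity_plane(x, y, vx, vy, vz, mask, center = c(0, 0),
                       radius = radius)
  attr(pl, "ground_truth") <- list(d = d, s = s, k = k, q_mls = q_mls,
                                   sfd = sfd_true)
  pl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a velocity plane to CSV
#'
#' One row per pixel with columns `x, y, vx, vy, vz, mask`; lumen centre and
#' radius are recorded in `#`-prefixed header comment lines.
#'
#' @param plane a [velocity_plane()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_velocity_plane <- function(plane, path) {
  stopifnot(inherits(plane, "velocity_plane"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# center %.17g %.17g", plane$center[1],
                     plane$center[2]), con)
  writeLines(sprintf("# radius %.17g", plane$radius), con)
  df <- data.frame(
    x = rep(plane$x, times = length(plane$y)),
    y = rep(plane$y, each = length(plane$x)),
    vx = as.numeric(plane$vx), vy = as.numeric(plane$vy),
    vz = as.numeric(plane$vz), mask = as.integer(plane$mask))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(sprintf, c(list("%.17g,%.17g,%.17g,%.17g,%.17g,%d"),
                                df)), con)
  invisible(path)
}

#' Read a velocity plane written by [write_velocity_plane()]
#'
#' @param path CSV path.
#' @param id optional plane identifier.
#' @return A [velocity_plane()].
#' @export
read_velocity_plane <- function(path, id = NA_character_) {
  lines <- readLines(path, n = 2)
  center <- as.numeric(strsplit(sub("# center ", "", lines[1]), " ")[[1]])
  radius <- as.numeric(sub("# radius ", "", lines[2]))
  df <- read.csv(path, comment.char = "#")
  x <- sort(unique(df$x)); y <- sort(unique(df$y))
  shape <- c(length(x), length(y))
  ord <- order(match(df$y, y), match(df$x, x))
  df <- df[ord, ]
  velocity_plane(x, y,
                 matrix(df$vx, shape[1], shape[2]),
                 matrix(df$vy, shape[1], shape[2]),
                 matrix(df$vz, shape[1], shape[2]),
                 matrix(df$mask == 1, shape[1], shape[2]),
                 center, radius, id = id)
}
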
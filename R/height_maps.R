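#' Generate a synthetic AFM-style height map
#'
#' Produces a height grid (nm) with a known lateral step, for validating the
#' surface-morphology metrics. For the analytic forms the true area ratio is
#' returned alongside the grid; for pillar fields the true pillar centres,
#' count and density are returned instead.
#'
#' Forms:
#' \describe{
#'   \item{\code{flat}}{constant height; true area ratio 1.}
#'   \item{\code{tilted-plane}}{\code{z = slope * x}; true ratio
#'     \code{sqrt(1 + slope^2)}.}
#'   \item{\code{sinusoid}}{\code{z = amplitude * sin(2*pi*x / period)};
#'     true ratio from 1-D quadrature of the surface-area integrand.}
#'   \item{\code{pillars}}{Gaussian bumps with heights drawn from
#'     \code{height_range_nm}, placed on a jittered lattice
#'     (\code{placement = "jittered-grid"}, the quasi-regular arrangement
#'     typical of self-organized etched nanopillars) or fully at random
#'     (\code{"poisson"}). Defaults mirror black-Si nanopillar surfaces:
#'     about 40 pillars/um^2, heights 520-800 nm, apex sigma 40 nm.}
#' }
#'
#' @param form one of \code{"flat"}, \code{"tilted-plane"},
#'   \code{"sinusoid"}, \code{"pillars"}.
#' @param params named list of form parameters (see Details); common
#'   entries: \code{n} grid side (default 64, min 8),
#'   \code{lateral_step_nm} (default 20).
#' @param seed integer seed (used by \code{"pillars"} only).
#' @return An object of class \code{height_map}: list with \code{heights}
#'   (nm matrix), \code{lateral_step_nm}, \code{true_ratio} (NA for
#'   pillars), and for pillars \code{truth} (centres, count,
#'   density_per_um2, heights_nm).
#' @export
generate_height_map <- function(form = c("flat", "tilted-plane", "sinusoid",
                                         "pillars"),
                                params = list(), seed = 1L) {
  form <- match.arg(form)
  p <- modifyList(list(n = 64L, lateral_step_nm = 20), params)
  n <- as.integer(p$n)
  if (n < 8L) stop("grid must be at least 8 x 8")
  step <- p$lateral_step_nm
  stopifnot(step > 0)
  x <- (seq_len(n) - 1) * step

  hm <- switch(form,
    "flat" = {
      z0 <- p$value %||% 0
      list(heights = matrix(z0, n, n), true_ratio = 1.0)
    },
    "tilted-plane" = {
      s <- p$slope %||% 1
      list(heights = matrix(rep(s * x, each = n), n, n),
           true_ratio = sqrt(1 + s^2))
    },
    "sinusoid" = {
      A <- p$amplitude_nm %||% 100
      P <- p$period_nm %||% (n * step / 4)
      z <- A * sin(2 * pi * x / P)
      w <- 2 * pi * A / P
      ratio <- integrate(function(u) sqrt(1 + w^2 * cos(u)^2),
                         0, 2 * pi)$value / (2 * pi)
      list(heights = matrix(rep(z, each = n), n, n), true_ratio = ratio)
    },
    "pillars" = {
      dens <- p$density_per_um2 %||% 40
      hr <- p$height_range_nm %||% c(520, 800)
      sig <- p$pillar_sigma_nm %||% 40
      placement <- p$placement %||% "jittered-grid"
      jit <- p$jitter_frac %||% 0.15
      side_nm <- n * step
      area_um2 <- (side_nm / 1000)^2
      with_local_seed(seed, {
        if (placement == "poisson") {
          np <- p$n_pillars %||% rpois(1L, dens * area_um2)
          cx <- runif(np, 0, side_nm)
          cy <- runif(np, 0, side_nm)
        } else {
          # self-organized etched pillar fields are quasi-regular: a
          # jittered lattice keeps apexes resolvable at realistic density
          k <- max(1L, round(sqrt(dens * area_um2)))
          sp <- side_nm / k
          g <- (seq_len(k) - 0.5) * sp
          cx <- rep(g, each = k) + runif(k * k, -jit, jit) * sp
          cy <- rep(g, times = k) + runif(k * k, -jit, jit) * sp
          np <- k * k
        }
        h <- runif(np, hr[1], hr[2])
        z <- matrix(0, n, n)
        for (i in seq_len(np)) {
          dx2 <- (x - cx[i])^2
          dy2 <- (x - cy[i])^2
          z <- z + h[i] * exp(-outer(dy2, dx2, "+") / (2 * sig^2))
        }
        list(heights = z, true_ratio = NA_real_,
             truth = list(centers_nm = cbind(x_nm = cx, y_nm = cy),
                          count = np, density_per_um2 = np / area_um2,
                          heights_nm = h, area_um2 = area_um2))
      })
    })

  structure(c(hm, list(lateral_step_nm = step, form = form,
                       seed = as.integer(seed))),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %s, %d x %d @ %g nm/step, true ratio %s\n",
              x$form, nrow(x$heights), ncol(x$heights), x$lateral_step_nm,
              format(x$true_ratio)))
  invisible(x)
}
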
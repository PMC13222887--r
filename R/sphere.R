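#' Generate a two-hemisphere spherical vertex lattice
#'
#' Places `V/2` vertices on each longitudinal half of the unit sphere using a
#' Fibonacci lattice (near-uniform spacing), with the right hemisphere the
#' exact sagittal mirror of the left. This geometry is the substrate for the
#' synthetic connectomes and for spin-rotation null models. Parcels are
#' contiguous equal-count latitude bands within each hemisphere; parcel `j`
#' in the left hemisphere is homologous to parcel `j + J/2` on the right.
#'
#' @param n_vertices Even vertex count V.
#' @param n_parcels Even parcel count J (default 14, i.e. a 7-network
#'   parcellation per hemisphere). Use `NULL` to skip parcellation.
#' @return A list with `vertices` (tibble: vertex, x, y, z, hemisphere,
#'   parcel) and `centroids` (tibble: parcel, hemisphere, x, y, z;
#'   unit-normalized mean of member vertices).
#' @export
gen_sphere <- function(n_vertices, n_parcels = 14L) {
  assert_that(n_vertices %% 2 == 0, "n_vertices must be even")
  n <- n_vertices / 2
  if (n == 1) {
    # degenerate lattice: one vertex per hemisphere, antipodal by convention
    lh <- matrix(c(-1, 0, 0), 1)
    rh <- matrix(c(1, 0, 0), 1)
  } else {
    i <- seq_len(n)
    z <- 1 - (2 * i - 1) / n
    golden <- (1 + sqrt(5)) / 2
    # compress azimuth into (pi/2, 3pi/2): the x < 0 longitudinal half
    phi <- pi / 2 + pi * ((i / golden) %% 1)
    r <- sqrt(pmax(0, 1 - z^2))
    lh <- cbind(r * cos(phi), r * sin(phi), z)
    rh <- lh
    rh[, 1] <- -rh[, 1]
  }
  coords <- rbind(lh, rh)
  coords <- coords / sqrt(rowSums(coords^2))
  hemi <- rep(c("L", "R"), each = n)
  vertices <- tibble(
    vertex = seq_len(n_vertices),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    hemisphere = hemi
  )
  if (!is.null(n_parcels)) {
    assert_that(n_parcels %% 2 == 0, "n_parcels must be even")
    per_hemi <- n_parcels / 2
    band <- function(ang) {
      # equal-count longitude wedges around the z axis (each parcel spans
      # the full latitude range), deterministic
      rk <- rank(ang, ties.method = "first")
      pmin(per_hemi, as.integer(ceiling(rk / (length(ang) / per_hemi))))
    }
    ang <- atan2(vertices$y, vertices$x)
    parcel <- integer(n_vertices)
    parcel[hemi == "L"] <- band(ang[hemi == "L"])
    parcel[hemi == "R"] <- band(ang[hemi == "R"]) + per_hemi
    vertices$parcel <- parcel
    centroids <- vertices |>
      group_by(.data$parcel, .data$hemisphere) |>
      summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                .groups = "drop") |>
      arrange(.data$parcel)
    nrm <- sqrt(centroids$x^2 + centroids$y^2 + centroids$z^2)
    centroids$x <- centroids$x / nrm
    centroids$y <- centroids$y / nrm
    centroids$z <- centroids$z / nrm
  } else {
    centroids <- NULL
  }
  list(vertices = vertices, centroids = centroids)
}

#' Build a parcellation object from a vertex table
#'
#' @param vertices Tibble with columns `vertex`, `parcel`, `hemisphere` (as
#'   produced by [gen_sphere()]).
#' @param name Label for the scheme.
#' @return A `parcellation` object: per-vertex labels, parcel count J, and
#'   per-parcel hemisphere.
#' @export
parcellation <- function(vertices, name = "custom") {
  labels <- vertices$parcel
  assert_that(!anyNA(labels), "every vertex must be labeled")
  ids <- sort(unique(labels))
  assert_that(all(tabulate(match(labels, ids)) > 0), "every parcel must be non-empty")
  hemi <- vapply(ids, function(j)
    unique(vertices$hemisphere[labels == j])[1], character(1))
  structure(list(name = name, labels = labels, J = length(ids),
                 parcels = ids, hemisphere = setNames(hemi, ids)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation '%s'>: %d parcels over %d vertices\n",
              x$name, x$J, length(x$labels)))
  invisible(x)
}
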
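# Structured triangulation of the unit disk: concentric rings k = 1..K at
# radius k/K with 16*k nodes each, plus the centre node; 16*K^2 linear
# triangles. Electrode e (1..16) sits at boundary node with angle
# 2*pi*(e-1)/16, which exists for every K.
.disk_mesh <- function(n_rings) {
  K <- as.integer(n_rings)
  nodes <- matrix(0, 1, 2)
  ring_ids <- vector("list", K + 1L)
  ring_ids[[1L]] <- 1L
  for (k in seq_len(K)) {
    m <- 16L * k
    th <- 2 * pi * (seq_len(m) - 1L) / m
    ids <- nrow(nodes) + seq_len(m)
    nodes <- rbind(nodes, (k / K) * cbind(cos(th), sin(th)))
    ring_ids[[k + 1L]] <- ids
  }
  # connect consecutive rings: advance along both closed chains by angle
  tris <- matrix(0L, 0L, 3L)
  for (k in seq_len(K)) {
    inner <- ring_ids[[k]]
    outer <- ring_ids[[k + 1L]]
    if (length(inner) == 1L) {
      m <- length(outer)
      tris <- rbind(tris, cbind(inner, outer, outer[c(2:m, 1L)]))
    } else {
      # two-pointer sweep over both closed chains at matching angular
      # fractions; emits length(inner) + length(outer) triangles
      ni <- length(inner); no <- length(outer)
      i <- 0L; j <- 0L
      new_tris <- matrix(0L, ni + no, 3L)
      r <- 0L
      while (i < ni || j < no) {
        r <- r + 1L
        if (j < no && (i >= ni || (j + 1) / no <= (i + 1) / ni)) {
          new_tris[r, ] <- c(inner[(i %% ni) + 1L], outer[(j %% no) + 1L],
                             outer[((j + 1L) %% no) + 1L])
          j <- j + 1L
        } else {
          new_tris[r, ] <- c(inner[(i %% ni) + 1L], outer[(j %% no) + 1L],
                             inner[((i + 1L) %% ni) + 1L])
          i <- i + 1L
        }
      }
      tris <- rbind(tris, new_tris)
    }
  }
  boundary <- ring_ids[[K + 1L]]
  electrodes <- boundary[seq.int(1L, by = K, length.out = 16L)]
  list(nodes = nodes, tris = tris, electrodes = electrodes, n_rings = K)
}

# element areas and shape-function gradients for linear triangles
.tri_geometry <- function(nodes, tris) {
  p1 <- nodes[tris[, 1L], , drop = FALSE]
  p2 <- nodes[tris[, 2L], , drop = FALSE]
  p3 <- nodes[tris[, 3L], , drop = FALSE]
  det <- (p2[, 1L] - p1[, 1L]) * (p3[, 2L] - p1[, 2L]) -
         (p3[, 1L] - p1[, 1L]) * (p2[, 2L] - p1[, 2L])
  area <- abs(det) / 2
  b <- cbind(p2[, 2L] - p3[, 2L], p3[, 2L] - p1[, 2L], p1[, 2L] - p2[, 2L]) / det
  c_ <- cbind(p3[, 1L] - p2[, 1L], p1[, 1L] - p3[, 1L], p2[, 1L] - p1[, 1L]) / det
  list(area = area, b = b, c = c_)
}

#' Build the linear EIT sensitivity model
#'
#' Solves the 2-D conductivity forward problem (point-electrode model, unit
#' background) on a structured unit-disk mesh with 16 equally spaced boundary
#' electrodes, for all 16 adjacent-pair injection patterns. The element
#' sensitivity (Jacobian) matrix `J` (208 x n_elements) follows from the
#' adjoint formula `J[(d,m), e] = -area_e * grad(u_d) . grad(u_m)`, which
#' makes drive/measurement reciprocity exact up to solver round-off. The
#' one-step Tikhonov inverse `B = (J'J + alpha * tr(J'J)/n * I)^{-1} J'`,
#' composed with element-to-pixel rasterization on a 32 x 32 circular-mask
#' grid, maps a 208-channel voltage difference to an impedance-change image.
#'
#' Channel ordering: for drive pair `d = 1..16` (electrodes d, d+1 mod 16),
#' the 13 adjacent measurement pairs `m` not touching the injecting
#' electrodes, in increasing m; 16 x 13 = 208 rows.
#'
#' @param mesh_resolution Target number of triangular elements (default 800;
#'   the structured mesh uses `16 * K^2` elements, K rings).
#' @param alpha Tikhonov regularization relative to `trace(J'J)/n`
#'   (default 1e-3).
#' @return An object of class `"sensitivity_model"`: mesh (`nodes`, `tris`,
#'   `electrodes`), `jacobian` (208 x n_elements), `inverse` (1024 x 208
#'   pixel-level B, zero rows off-mask), `alpha`, `baseline` (homogeneous
#'   boundary voltages, 208), `channels` (drive/measurement pair table),
#'   `pixel_element` (element index per pixel, 0 off-mask) and `mask`
#'   (32 x 32 logical).
#' @export
build_sensitivity <- function(mesh_resolution = 800, alpha = 1e-3) {
  if (mesh_resolution < 200) stop("mesh_resolution must be >= 200 elements")
  if (alpha <= 0) stop("alpha must be positive")
  K <- max(2L, as.integer(round(sqrt(mesh_resolution / 16))))
  mesh <- .disk_mesh(K)
  geo <- .tri_geometry(mesh$nodes, mesh$tris)
  n_nodes <- nrow(mesh$nodes)
  n_el <- nrow(mesh$tris)

  # assemble the unit-conductivity stiffness matrix
  Kmat <- matrix(0, n_nodes, n_nodes)
  for (e in seq_len(n_el)) {
    v <- mesh$tris[e, ]
    Ke <- geo$area[e] * (outer(geo$b[e, ], geo$b[e, ]) +
                         outer(geo$c[e, ], geo$c[e, ]))
    Kmat[v, v] <- Kmat[v, v] + Ke
  }
  # ground the centre node and factor once for all 16 drive patterns
  free <- 2L:n_nodes
  R <- chol(Kmat[free, free])
  solve_pot <- function(rhs) {
    u <- numeric(n_nodes)
    u[free] <- backsolve(R, forwardsolve(t(R), rhs[free]))
    u
  }
  el <- mesh$electrodes
  U <- matrix(0, n_nodes, 16L)       # potential field per drive pair
  for (d in seq_len(16L)) {
    rhs <- numeric(n_nodes)
    rhs[el[d]] <- 1
    rhs[el[(d %% 16L) + 1L]] <- -1
    U[, d] <- solve_pot(rhs)
  }
  if (any(!is.finite(U))) stop("singular forward system (degenerate mesh)")

  # element-wise potential gradients per pattern: n_el x 2 x 16
  GX <- matrix(0, n_el, 16L)
  GY <- matrix(0, n_el, 16L)
  for (d in seq_len(16L)) {
    uv <- matrix(U[mesh$tris, d], n_el, 3L)
    GX[, d] <- rowSums(geo$b * uv)
    GY[, d] <- rowSums(geo$c * uv)
  }

  # channel table: measurement pairs not touching the injecting electrodes
  channels <- do.call(rbind, lapply(seq_len(16L), function(d) {
    excl <- c((d - 2L) %% 16L + 1L, d, (d %% 16L) + 1L)
    data.frame(drive = d, meas = setdiff(seq_len(16L), excl))
  }))

  baseline <- mapply(function(d, m) {
    U[el[m], d] - U[el[(m %% 16L) + 1L], d]
  }, channels$drive, channels$meas)

  J <- matrix(0, nrow(channels), n_el)
  for (r in seq_len(nrow(channels))) {
    d <- channels$drive[r]; m <- channels$meas[r]
    J[r, ] <- -geo$area * (GX[, d] * GX[, m] + GY[, d] * GY[, m])
  }

  tr <- sum(J * J)
  M <- crossprod(J)
  diag(M) <- diag(M) + alpha * tr / n_el
  B_elem <- solve(M, t(J))           # n_el x 208

  # rasterize: 32 x 32 pixel centres, element containing each in-disk centre
  gx <- (seq_len(32L) - 0.5) / 16 - 1
  centres <- cbind(rep(gx, times = 32L), rep(gx, each = 32L))
  mask32 <- matrix(sqrt(rowSums(centres^2)) <= 1, 32L, 32L)
  pixel_element <- integer(1024L)
  inside <- which(as.vector(mask32))
  cent_el <- cbind(
    (mesh$nodes[mesh$tris[, 1L], 1L] + mesh$nodes[mesh$tris[, 2L], 1L] +
       mesh$nodes[mesh$tris[, 3L], 1L]) / 3,
    (mesh$nodes[mesh$tris[, 1L], 2L] + mesh$nodes[mesh$tris[, 2L], 2L] +
       mesh$nodes[mesh$tris[, 3L], 2L]) / 3
  )
  for (p in inside) {
    pt <- centres[p, ]
    hit <- 0L
    for (e in seq_len(n_el)) {
      v <- mesh$tris[e, ]
      l <- .barycentric(pt, mesh$nodes[v, ])
      if (all(l > -1e-9)) { hit <- e; break }
    }
    if (hit == 0L) {  # ring gap due to polygonal boundary: nearest centroid
      hit <- which.min((cent_el[, 1L] - pt[1L])^2 + (cent_el[, 2L] - pt[2L])^2)
    }
    pixel_element[p] <- hit
  }
  B_pix <- matrix(0, 1024L, nrow(channels))
  nz <- pixel_element > 0L
  B_pix[nz, ] <- B_elem[pixel_element[nz], ]

  structure(
    list(nodes = mesh$nodes, tris = mesh$tris, electrodes = el,
         jacobian = J, inverse = B_pix, alpha = alpha, baseline = baseline,
         channels = channels, pixel_element = pixel_element, mask = mask32,
         n_elements = n_el, areas = geo$area, centroids = cent_el),
    class = "sensitivity_model"
  )
}

.barycentric <- function(pt, tri) {
  d <- (tri[2L, 2L] - tri[3L, 2L]) * (tri[1L, 1L] - tri[3L, 1L]) +
       (tri[3L, 1L] - tri[2L, 1L]) * (tri[1L, 2L] - tri[3L, 2L])
  l1 <- ((tri[2L, 2L] - tri[3L, 2L]) * (pt[1L] - tri[3L, 1L]) +
         (tri[3L, 1L] - tri[2L, 1L]) * (pt[2L] - tri[3L, 2L])) / d
  l2 <- ((tri[3L, 2L] - tri[1L, 2L]) * (pt[1L] - tri[3L, 1L]) +
         (tri[1L, 1L] - tri[3L, 1L]) * (pt[2L] - tri[3L, 2L])) / d
  c(l1, l2, 1 - l1 - l2)
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat("EIT sensitivity model (unit disk, 16 electrodes, adjacent drive)\n")
  cat("  elements:", x$n_elements, " nodes:", nrow(x$nodes),
      " channels:", nrow(x$channels), "\n")
  cat("  Tikhonov alpha (relative):", x$alpha, "\n")
  invisible(x)
}

#' Recompute the regularized inverse for a new alpha
#'
#' Rebuilds the pixel-level inverse from the stored Jacobian; used to study
#' the noise-amplification / resolution trade-off without re-solving the
#' forward problem.
#'
#' @param model A `"sensitivity_model"`.
#' @param alpha New relative regularization parameter.
#' @return The model with updated `inverse` and `alpha`.
#' @export
update_alpha <- function(model, alpha) {
  stopifnot(inherits(model, "sensitivity_model"))
  if (alpha <= 0) stop("alpha must be positive")
  J <- model$jacobian
  M <- crossprod(J)
  diag(M) <- diag(M) + alpha * sum(J * J) / model$n_elements
  B_elem <- solve(M, t(J))
  B_pix <- matrix(0, 1024L, nrow(model$channels))
  nz <- model$pixel_element > 0L
  B_pix[nz, ] <- B_elem[model$pixel_element[nz], ]
  model$inverse <- B_pix
  model$alpha <- alpha
  model
}

#' Linearized forward map
#'
#' Boundary-voltage change `J %*% delta_sigma` for a conductivity
#' perturbation on the mesh elements; linear by construction.
#'
#' @param model A `"sensitivity_model"`.
#' @param delta_sigma Numeric vector, one value per mesh element.
#' @return Numeric 208-vector of voltage changes.
#' @export
forward_frame <- function(model, delta_sigma) {
  stopifnot(inherits(model, "sensitivity_model"))
  if (length(delta_sigma) != model$n_elements) {
    stop("delta_sigma must have length ", model$n_elements)
  }
  as.numeric(model$jacobian %*% delta_sigma)
}

#' Reconstruct a difference image
#'
#' One-step linear difference imaging `y = B (x_c - x_ref)`: the regularized
#' inverse maps the boundary-voltage change between the current and the
#' reference frame to a 32 x 32 impedance-change image (dimensionless; NA
#' outside the circular mask). Zero difference gives an exactly zero image.
#'
#' @param model A `"sensitivity_model"`.
#' @param frame Current 208-channel frame.
#' @param reference Reference 208-channel frame.
#' @return An object of class `"eit_image"` with `pixels` (32 x 32 matrix).
#' @export
reconstruct <- function(model, frame, reference) {
  stopifnot(inherits(model, "sensitivity_model"))
  if (length(frame) != 208L || length(reference) != 208L) {
    stop("frames must have 208 channels")
  }
  if (any(!is.finite(frame)) || any(!is.finite(reference))) {
    stop("non-finite voltage in frame or reference")
  }
  y <- as.numeric(model$inverse %*% (frame - reference))
  px <- matrix(y, 32L, 32L)
  px[!model$mask] <- NA_real_
  structure(list(pixels = px, mask = model$mask), class = "eit_image")
}

#' Reconstruct every frame of a series
#'
#' @param model A `"sensitivity_model"`.
#' @param frames A [frame_series()].
#' @param reference_policy `"first_frame"` (default), `"fixed_index"`, or
#'   `"mean_window"` (mean of frames `window`).
#' @param index Reference frame for `"fixed_index"`.
#' @param window Frame indices averaged for `"mean_window"`.
#' @return List of `"eit_image"` objects, one per frame, with the policy in
#'   attribute `"reference_policy"`.
#' @export
reconstruct_series <- function(model, frames,
                               reference_policy = c("first_frame",
                                                    "fixed_index",
                                                    "mean_window"),
                               index = 1L, window = NULL) {
  reference_policy <- match.arg(reference_policy)
  stopifnot(inherits(frames, "frame_series"))
  if (nrow(frames$data) == 0L) stop("empty frame series")
  ref <- switch(reference_policy,
    first_frame = frames$data[1L, ],
    fixed_index = frames$data[index, ],
    mean_window = colMeans(frames$data[window, , drop = FALSE])
  )
  out <- lapply(seq_len(nrow(frames$data)), function(i) {
    reconstruct(model, frames$data[i, ], ref)
  })
  attr(out, "reference_policy") <- reference_policy
  out
}

#' @export
print.eit_image <- function(x, ...) {
  v <- x$pixels[x$mask]
  cat("EIT difference image 32 x 32 (", sum(x$mask), " on-mask pixels)\n",
      sep = "")
  cat("  range: [", format(min(v), digits = 4), ", ",
      format(max(v), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.eit_image <- function(x, ...) {
  graphics::image(seq_len(32L), seq_len(32L), x$pixels, asp = 1,
                  xlab = "", ylab = "", ...)
  invisible(x)
}

#' Read / write a 32 x 32 image as CSV
#'
#' Off-mask pixels are written as `nan`.
#'
#' @param image An `"eit_image"` or 32 x 32 matrix.
#' @param path CSV path.
#' @return `write_image_csv` invisibly returns `path`; `read_image_csv`
#'   returns an `"eit_image"`.
#' @export
write_image_csv <- function(image, path) {
  px <- if (inherits(image, "eit_image")) image$pixels else image
  utils::write.table(px, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "nan")
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  px <- as.matrix(utils::read.table(path, sep = ",",
                                    na.strings = c("nan", "NaN", "NA")))
  dimnames(px) <- NULL
  structure(list(pixels = px, mask = is.finite(px)), class = "eit_image")
}
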
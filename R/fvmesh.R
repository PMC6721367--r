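# Finite-volume machinery shared by the diffusion and bioheat solvers.
#
# Both equations have the form  -div(gamma grad u) + sigma u = q  with a
# Robin condition  flux_out = c1 (u_surface - u_inf)  on selected boundary
# sides. Discretization is cell-centered with harmonic-mean face
# conductances, which makes the scheme locally conservative and yields a
# symmetric M-matrix (discrete maximum principle, non-negative solutions
# for non-negative sources).

# Face list of a structured phantom: internal faces (a, b, area) and
# boundary faces (cell, area, side in {surface, bottom, lateral}).
fv_mesh <- function(phantom) {
  h <- phantom$spacing
  switch(phantom$grid_kind,
    slab_1d = {
      nz <- phantom$dims[["nz"]]
      a <- seq_len(nz - 1L)
      list(faces = list(a = a, b = a + 1L, area = rep(1, nz - 1L)),
           bfaces = list(cell = c(1L, nz), area = c(1, 1),
                         side = c("surface", "bottom")))
    },
    axisymmetric_2d = {
      nr <- phantom$dims[["nr"]]; nz <- phantom$dims[["nz"]]
      idx <- function(i, j) i + (j - 1L) * nr
      r_cent <- (seq_len(nr) - 0.5) * h
      # radial faces between (i, j) and (i+1, j), area 2 pi (i h) h
      i_r <- rep(seq_len(nr - 1L), times = nz)
      j_r <- rep(seq_len(nz), each = nr - 1L)
      a_r <- idx(i_r, j_r); b_r <- a_r + 1L
      area_r <- 2 * pi * (i_r * h) * h
      # axial faces between (i, j) and (i, j+1), area 2 pi r_i h
      i_z <- rep(seq_len(nr), times = nz - 1L)
      j_z <- rep(seq_len(nz - 1L), each = nr)
      a_z <- idx(i_z, j_z); b_z <- a_z + nr
      area_z <- 2 * pi * r_cent[i_z] * h
      ring_area <- 2 * pi * r_cent * h
      list(faces = list(a = c(a_r, a_z), b = c(b_r, b_z),
                        area = c(area_r, area_z)),
           bfaces = list(
             cell = c(idx(seq_len(nr), 1L), idx(seq_len(nr), nz),
                      idx(nr, seq_len(nz))),
             area = c(ring_area, ring_area,
                      rep(2 * pi * (nr * h) * h, nz)),
             side = rep(c("surface", "bottom", "lateral"),
                        times = c(nr, nr, nz))))
    },
    voxel_3d = {
      nx <- phantom$dims[["nx"]]; ny <- phantom$dims[["ny"]]
      nz <- phantom$dims[["nz"]]
      idx <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
      grid2 <- function(n1, n2) list(rep(seq_len(n1), times = n2),
                                     rep(seq_len(n2), each = n1))
      a <- integer(0); b <- integer(0)
      # x faces
      g <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny),
                       k = seq_len(nz))
      a <- c(a, idx(g$i, g$j, g$k)); b <- c(b, idx(g$i + 1L, g$j, g$k))
      # y faces
      g <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1L),
                       k = seq_len(nz))
      a <- c(a, idx(g$i, g$j, g$k)); b <- c(b, idx(g$i, g$j + 1L, g$k))
      # z faces
      g <- expand.grid(i = seq_len(nx), j = seq_len(ny),
                       k = seq_len(nz - 1L))
      a <- c(a, idx(g$i, g$j, g$k)); b <- c(b, idx(g$i, g$j, g$k + 1L))
      gxy <- expand.grid(i = seq_len(nx), j = seq_len(ny))
      top <- idx(gxy$i, gxy$j, 1L); bot <- idx(gxy$i, gxy$j, nz)
      gxz <- expand.grid(i = seq_len(nx), k = seq_len(nz))
      gyz <- expand.grid(j = seq_len(ny), k = seq_len(nz))
      lat <- c(idx(gxz$i, 1L, gxz$k), idx(gxz$i, ny, gxz$k),
               idx(1L, gyz$j, gyz$k), idx(nx, gyz$j, gyz$k))
      list(faces = list(a = a, b = b, area = rep(h^2, length(a))),
           bfaces = list(cell = c(top, bot, lat),
                         area = rep(h^2, length(top) * 2 + length(lat)),
                         side = rep(c("surface", "bottom", "lateral"),
                                    times = c(length(top), length(bot),
                                              length(lat)))))
    })
}

# Assemble the sparse operator A u = q V + b_bc for
#   -div(gamma grad u) + sigma u = q,   flux_out = c1 (u_face - u_inf).
# `robin` is a named list side -> list(c1, u_inf); omitted sides are
# insulated. Returns A (symmetric sparse), the constant boundary load b_bc,
# and the boundary conductances for flux extraction.
fv_operator <- function(phantom, gamma, sigma, robin) {
  mesh <- fv_mesh(phantom)
  vol <- cell_volumes(phantom)
  n <- n_cells(phantom)
  h <- phantom$spacing
  fa <- mesh$faces
  # harmonic-mean conductance; gamma = 0 on either side blocks the face
  ga <- gamma[fa$a]; gb <- gamma[fa$b]
  ok <- ga > 0 & gb > 0
  g_face <- numeric(length(fa$a))
  g_face[ok] <- fa$area[ok] / ((h / 2) / ga[ok] + (h / 2) / gb[ok])

  bf <- mesh$bfaces
  c1 <- vapply(bf$side, function(s) {
    r <- robin[[s]]; if (is.null(r)) 0 else r$c1
  }, numeric(1))
  u_inf <- vapply(bf$side, function(s) {
    r <- robin[[s]]; if (is.null(r)) 0 else r$u_inf
  }, numeric(1))
  gcell <- gamma[bf$cell]
  g_b <- numeric(length(bf$cell))
  act <- c1 > 0 & gcell > 0
  g_b[act] <- bf$area[act] /
    (ifelse(is.finite(c1[act]), 1 / c1[act], 0) + (h / 2) / gcell[act])

  diag_entries <- sigma * vol
  if (length(g_face)) {
    diag_add <- numeric(n)
    tmp <- rowsum(c(g_face, g_face), c(fa$a, fa$b))
    diag_add[as.integer(rownames(tmp))] <- tmp[, 1]
    diag_entries <- diag_entries + diag_add
  }
  if (length(g_b)) {
    tmp <- rowsum(g_b, bf$cell)
    diag_b <- numeric(n)
    diag_b[as.integer(rownames(tmp))] <- tmp[, 1]
    diag_entries <- diag_entries + diag_b
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), fa$a, fa$b),
    j = c(seq_len(n), fa$b, fa$a),
    x = c(diag_entries, -g_face, -g_face),
    dims = c(n, n))
  b_bc <- numeric(n)
  if (length(g_b)) {
    tmp <- rowsum(g_b * u_inf, bf$cell)
    b_bc[as.integer(rownames(tmp))] <- tmp[, 1]
  }
  list(A = Matrix::forceSymmetric(A), b_bc = b_bc, vol = vol,
       bflux = list(cell = bf$cell, g = g_b, u_inf = u_inf,
                    side = bf$side))
}

# Outward boundary flow (W) given a solution vector.
fv_boundary_outflow <- function(op, u) {
  sum(op$bflux$g * (u[op$bflux$cell] - op$bflux$u_inf))
}

fv_solve <- function(op, rhs) {
  as.numeric(Matrix::solve(op$A, rhs))
}
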
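# Shared fixtures.  Simulated tissues are built once per test run and
# cached; everything is generated in code (no stored data).

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

spec_A <- function() model_spec("anisotropic_spring", "A")
spec_E <- function() model_spec("anisotropic_spring", "E")

# reference anisotropic-spring ground truth
ref_par <- function() reference_params()

# small equilibrated model-A tissue (6x6 cells)
simA_small <- function() {
  cached("simA_small",
         simulate_tissue(spec_A(), ref_par(), 6, 6, t_end = 500, seed = 42))
}

# small equilibrated constant-tension (model E) tissue: isotropic, exact
# gradient flow, converges essentially to machine precision
simE_small <- function() {
  cached("simE_small",
         simulate_tissue(spec_E(),
                         mech_params(lambda0 = 0.2, k = 1, A0 = 1),
                         5, 5, t_end = 500, seed = 3))
}

# conventional isotropic tissue, typical parameter set
simC_conv <- function() {
  cached("simC_conv",
         simulate_tissue(model_spec("conventional", "isotropic"),
                         mech_params(lambda0 = 0.12, gamma0 = 0.04, k = 1),
                         6, 6, t_end = 500, seed = 5))
}

# rectangular grid of nr x nc unit squares (w, h cell size)
grid_tissue <- function(nr, nc, w = 1, h = 1) {
  vid <- function(r, c) r * (nc + 1) + c # 0-based
  rows <- 0:nr; cols <- 0:nc
  vertices <- expand.grid(c = cols, r = rows)
  vertices <- data.frame(id = vid(vertices$r, vertices$c),
                         x = vertices$c * w, y = vertices$r * h)
  hor <- expand.grid(c = 0:(nc - 1), r = rows)
  ver <- expand.grid(c = cols, r = 0:(nr - 1))
  junctions <- data.frame(
    id = seq_len(nrow(hor) + nrow(ver)) - 1L,
    v1 = c(vid(hor$r, hor$c), vid(ver$r, ver$c)),
    v2 = c(vid(hor$r, hor$c + 1), vid(ver$r + 1, ver$c)))
  cells <- expand.grid(c = 0:(nc - 1), r = 0:(nr - 1))
  loops <- lapply(seq_len(nrow(cells)), function(i) {
    r <- cells$r[i]; c <- cells$c[i]
    as.integer(c(vid(r, c), vid(r, c + 1), vid(r + 1, c + 1), vid(r + 1, c)))
  })
  tissue(vertices, junctions,
         tibble::tibble(id = seq_along(loops) - 1L, vertex_loop = loops))
}

# perfect regular hexagonal lattice (pointy-top), nr x nc cells
hex_lattice_tissue <- function(nr = 4, nc = 4, s = 0.6204) {
  polys <- list()
  for (r in 0:(nr - 1)) for (c in 0:(nc - 1)) {
    cx <- sqrt(3) * s * (c + (r %% 2) / 2)
    cy <- 1.5 * s * r
    ang <- pi / 6 + (0:5) * pi / 3
    polys[[length(polys) + 1]] <- cbind(cx + s * cos(ang), cy + s * sin(ang))
  }
  xy <- do.call(rbind, polys)
  mp <- epimech:::merge_points(xy, tol = 1e-8)
  off <- c(0, cumsum(vapply(polys, nrow, 0L)))
  loops <- lapply(seq_along(polys), function(i) mp$map[(off[i] + 1):off[i + 1]])
  epimech:::state_to_tissue(mp$pos, loops)
}

# four-cell pinwheel with a short vertical central junction (id 0) inside a
# 2*hw x 2*hh box; both central-edge endpoints are interior and degree 3
pinwheel_tissue <- function(hw, hh, h = 0.02) {
  v <- data.frame(id = 0:5,
                  x = c(-hw, hw, hw, -hw, 0, 0),
                  y = c(-hh, -hh, hh, hh, -h, h))
  j <- data.frame(id = 0:8,
                  v1 = c(4, 4, 4, 5, 5, 0, 1, 2, 3),
                  v2 = c(5, 0, 1, 2, 3, 1, 2, 3, 0))
  cl <- tibble::tibble(id = 0:3,
                       vertex_loop = list(c(0L, 4L, 5L, 3L), c(4L, 1L, 2L, 5L),
                                          c(0L, 1L, 4L), c(5L, 2L, 3L)))
  tissue(v, j, cl)
}

# random valid parameter set for property tests
random_params <- function() {
  mech_params(lambda0 = runif(1, 0.1, 2), mu0 = runif(1, 0, 0.8),
              phi0 = runif(1, 0, pi), lambda1 = runif(1, 0, 0.5),
              mu1 = runif(1, 0, 0.95), phi1 = runif(1, 0, pi),
              gamma0 = runif(1, 0, 0.5), mu_gamma = runif(1, 0, 0.8),
              phi_gamma = runif(1, 0, pi), k = runif(1, 0.5, 4))
}
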
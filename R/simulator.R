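#' Generate an initial Voronoi tissue tile
#'
#' Builds the starting configuration for cell vertex model runs: a bounded
#' Voronoi tessellation of `n_rows * n_cols` uniformly random centroids in a
#' rectangle scaled so that the mean cell area equals `A0`. The boundary is
#' free (no constraint is attached to the hull).
#'
#' @param n_rows,n_cols Cell counts along the two tile axes (each >= 2).
#' @param A0 Target mean cell area.
#' @param seed Optional RNG seed; the same seed reproduces the tile exactly.
#' @return A [tissue()] with `n_rows * n_cols` cells.
#' @examples
#' tile <- generate_initial_tile(3, 3, seed = 1)
#' mean(cell_geometry(tile)$area) # 1
#' @export
generate_initial_tile <- function(n_rows, n_cols, A0 = 1, seed = NULL) {
  if (n_rows < 2 || n_cols < 2) abort("tile counts must be >= 2",
                                      class = "epimech_config_error")
  if (A0 <= 0) abort("A0 must be positive", class = "epimech_config_error")
  if (!is.null(seed)) set.seed(seed)
  vm <- voronoi_mesh(n_rows, n_cols, A0)
  state_to_tissue(vm$pos, vm$loops)
}

# simulation-side pressure: -dU/dA of the k/2 (A - A0)^2 term
sim_pressure <- function(params, A) -params$k * (A - params$A0)

check_simulable <- function(spec, params) {
  if (spec$pressure_form != "linear") {
    abort("the simulator uses the quadratic area term, i.e. the linear pressure form",
          class = "epimech_config_error")
  }
  if (spec$family == "conventional" && params$mu_gamma != 0) {
    abort("anisotropic cortical elasticity has no perimeter-energy form; simulation supports mu_gamma = 0 only",
          class = "epimech_config_error")
  }
  invisible(TRUE)
}

# virtual work from flattened mesh + geometry; theta optionally frozen
u0_state <- function(fm, g, spec, params, theta = NULL) {
  th <- theta %||% g$th
  area_term <- sum(params$k / 2 * (g$A - params$A0)^2)
  if (spec$family == "anisotropic_spring") {
    lam0 <- switch(spec$variant,
      A = , B = , D = aniso_coef(params$lambda0, params$mu0, params$phi0, th),
      C = , E = rep(params$lambda0, length(g$l)))
    lam1 <- switch(spec$variant,
      A = aniso_coef(params$lambda1, params$mu1, params$phi1, th),
      B = , C = rep(params$lambda1, length(g$l)),
      D = , E = 0)
    sum(lam0 * g$l - lam1 * g$l^2 / 2) + area_term
  } else {
    lam0 <- switch(spec$variant,
      both_aniso = , line_aniso = aniso_coef(params$lambda0, params$mu0, params$phi0, th),
      elasticity_aniso = , isotropic = rep(params$lambda0, length(g$l)))
    sum(lam0 * g$l) + sum(params$gamma0 / 2 * g$perim^2) + area_term
  }
}

# per-junction summed perimeters of adjacent cells (conventional family)
junction_L_sum <- function(fm, g) {
  L1 <- ifelse(is.na(fm$jcells[, 1]), 0, g$perim[fm$jcells[, 1]])
  L2 <- ifelse(is.na(fm$jcells[, 2]), 0, g$perim[fm$jcells[, 2]])
  L1 + L2
}

# net force on every vertex; anisotropy factors frozen at current angles
state_forces <- function(fm, g, spec, params, pos) {
  Ls <- if (spec$family == "conventional") junction_L_sum(fm, g) else NULL
  Tj <- tension(spec, params, g$l, g$th, Ls)
  inv_l <- ifelse(g$l > 0, 1 / g$l, 0)
  ux <- g$d[, 1] * inv_l; uy <- g$d[, 2] * inv_l
  Fv <- matrix(0, fm$V, 2)
  ft <- rowsum(cbind(c(Tj * ux, -Tj * ux), c(Tj * uy, -Tj * uy)),
               c(fm$ej[, 1], fm$ej[, 2]))
  Fv[as.integer(rownames(ft)), ] <- ft
  if (fm$C > 0) {
    P <- sim_pressure(params, g$A)
    nxt <- fm$loop_next; prv <- fm$loop_prev
    gx <- 0.5 * (pos[fm$loop_v[nxt], 2] - pos[fm$loop_v[prv], 2])
    gy <- 0.5 * (pos[fm$loop_v[prv], 1] - pos[fm$loop_v[nxt], 1])
    Pc <- P[fm$loop_cell]
    fp <- rowsum(cbind(Pc * gx, Pc * gy), fm$loop_v)
    ip <- as.integer(rownames(fp))
    Fv[ip, ] <- Fv[ip, ] + fp
  }
  Fv
}

#' Virtual work of a tissue configuration
#'
#' Evaluates the energy whose relaxation defines the cell vertex model.
#' For the anisotropic spring family,
#' \deqn{U_0 = \sum_{[ij]} \{\Lambda_0(\theta_{ij}) l_{ij} -
#'   \tfrac12 \Lambda_1(\theta_{ij}) l_{ij}^2\} +
#'   \sum_i \tfrac k2 (A_i - A_0)^2,}
#' and for the conventional family
#' \deqn{U_0 = \sum_{[ij]} \Lambda_0 l_{ij} + \sum_i \tfrac\Gamma2 L_i^2 +
#'   \sum_i \tfrac k2 (A_i - A_0)^2.}
#' Differentiating by \eqn{l_{ij}} and \eqn{A_i} recovers [tension()] and
#' the pressure \eqn{-k(A_i - A_0)}.
#'
#' @param tis A [tissue()].
#' @param spec A [model_spec()].
#' @param params A [mech_params()] (ground truth for the simulation).
#' @return Scalar energy.
#' @examples
#' virtual_work(unit_square_tissue(), model_spec(variant = "E"),
#'              mech_params(lambda0 = 1, k = 1, A0 = 1)) # 4
#' @export
virtual_work <- function(tis, spec, params) {
  check_simulable(spec, params)
  fm <- mesh_data(tis, strict = FALSE)
  g <- flat_geometry(fm)
  u0_state(fm, g, spec, params)
}

#' Net mechanical force on each vertex
#'
#' The negative gradient of [virtual_work()] with the anisotropy factors
#' \eqn{\Lambda(\theta)} held frozen at the current junction angles: each
#' incident junction pulls the vertex toward its far endpoint with its
#' tension, and each adjacent cell pushes with its pressure times the
#' shoelace area gradient.
#'
#' @inheritParams virtual_work
#' @return Tibble with columns `id`, `fx`, `fy`.
#' @export
vertex_forces <- function(tis, spec, params) {
  check_simulable(spec, params)
  fm <- mesh_data(tis, strict = FALSE)
  g <- flat_geometry(fm)
  Fv <- state_forces(fm, g, spec, params, fm$pos)
  tibble(id = tis$vertices$id, fx = Fv[, 1], fy = Fv[, 2])
}

insert_after <- function(loop, at, value) {
  i <- match(at, loop)
  append(loop, value, after = i)
}

# attempt a T1 flip of junction row `jrow` of fm; returns NULL if the move
# is not allowed, otherwise list(loops, pos, du)
t1_trial <- function(fm, pos, loops, jrow, spec, params) {
  if (fm$boundary_j[jrow]) return(NULL)
  a <- fm$ej[jrow, 1]; b <- fm$ej[jrow, 2]
  if (fm$degree[a] != 3L || fm$degree[b] != 3L) return(NULL)
  if (fm$boundary_v[a] || fm$boundary_v[b]) return(NULL)
  XY <- fm$jcells[jrow, ]
  cells_a <- unique(fm$loop_cell[fm$loop_v == a])
  cells_b <- unique(fm$loop_cell[fm$loop_v == b])
  Z <- setdiff(cells_a, XY); W <- setdiff(cells_b, XY)
  if (length(Z) != 1L || length(W) != 1L || Z == W) return(NULL)
  X <- XY[1]; Y <- XY[2]
  if (length(loops[[X]]) < 4L || length(loops[[Y]]) < 4L) return(NULL)

  loop_neighbors <- function(cell, v) {
    lp <- loops[[cell]]; i <- match(v, lp); n <- length(lp)
    c(lp[if (i == 1) n else i - 1L], lp[if (i == n) 1L else i + 1L])
  }
  q <- setdiff(loop_neighbors(Y, a), b) # a's other neighbour in Y
  r <- setdiff(loop_neighbors(X, b), a) # b's other neighbour in X
  if (length(q) != 1L || length(r) != 1L) return(NULL)

  new_loops <- loops
  new_loops[[X]] <- setdiff(loops[[X]], b)
  new_loops[[Y]] <- setdiff(loops[[Y]], a)
  # Z's boundary path a--q becomes a--b--q: insert b between a and q,
  # whichever of the two is the loop successor of the other
  lpZ <- loops[[Z]]
  iZ <- match(a, lpZ); nZ <- length(lpZ)
  nxtZ <- lpZ[if (iZ == nZ) 1L else iZ + 1L]
  new_loops[[Z]] <- insert_after(lpZ, if (nxtZ == q) a else q, b)
  # W's boundary path b--r becomes b--a--r: insert a between b and r
  lpW <- loops[[W]]
  iW <- match(b, lpW); nW <- length(lpW)
  nxtW <- lpW[if (iW == nW) 1L else iW + 1L]
  new_loops[[W]] <- insert_after(lpW, if (nxtW == r) b else r, a)

  # rotate the edge 90 degrees about its midpoint, length preserved;
  # the surviving member of X (vertex a) goes to X's side
  d <- pos[b, ] - pos[a, ]
  mid <- (pos[a, ] + pos[b, ]) / 2
  perp <- c(-d[2], d[1]) / 2
  cX <- colMeans(pos[loops[[X]], , drop = FALSE])
  if (sum((cX - mid) * perp) < 0) perp <- -perp
  new_pos <- pos
  new_pos[a, ] <- mid + perp
  new_pos[b, ] <- mid - perp
  list(loops = new_loops, pos = new_pos, cells = c(X, Y, Z, W))
}

# Energy restricted to a set of cells (their edges, deduplicated, plus their
# perimeter/area terms).  A T1 flip moves only the two edge vertices, so all
# length, angle, perimeter and area changes are confined to the four cells
# returned by t1_trial; the difference of local_u before/after equals the
# full virtual-work difference.  Returns +Inf for an invalid (non-convex
# collapse) trial so callers reject it.
local_u <- function(loops, pos, cells, spec, params) {
  V <- nrow(pos)
  ek <- numeric(0); e1 <- integer(0); e2 <- integer(0)
  u_cells <- 0
  conventional <- spec$family == "conventional"
  for (ci in cells) {
    lp <- loops[[ci]]
    nx <- c(lp[-1], lp[1])
    xs <- pos[lp, 1]; ys <- pos[lp, 2]
    A <- sum(xs * pos[nx, 2] - pos[nx, 1] * ys) / 2
    if (A <= 0) return(Inf)
    u_cells <- u_cells + params$k / 2 * (A - params$A0)^2
    if (conventional) {
      L <- sum(sqrt((pos[nx, 1] - xs)^2 + (pos[nx, 2] - ys)^2))
      u_cells <- u_cells + params$gamma0 / 2 * L^2
    }
    ek <- c(ek, edge_key(lp, nx, V)); e1 <- c(e1, lp); e2 <- c(e2, nx)
  }
  keep <- !duplicated(ek)
  e1 <- e1[keep]; e2 <- e2[keep]
  dx <- pos[e2, 1] - pos[e1, 1]; dy <- pos[e2, 2] - pos[e1, 2]
  l <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  if (spec$family == "anisotropic_spring") {
    lam0 <- switch(spec$variant,
      A = , B = , D = aniso_coef(params$lambda0, params$mu0, params$phi0, th),
      C = , E = rep(params$lambda0, length(l)))
    lam1 <- switch(spec$variant,
      A = aniso_coef(params$lambda1, params$mu1, params$phi1, th),
      B = , C = rep(params$lambda1, length(l)),
      D = , E = 0)
    u_cells + sum(lam0 * l - lam1 * l^2 / 2)
  } else {
    lam0 <- switch(spec$variant,
      both_aniso = , line_aniso = aniso_coef(params$lambda0, params$mu0, params$phi0, th),
      elasticity_aniso = , isotropic = rep(params$lambda0, length(l)))
    u_cells + sum(lam0 * l)
  }
}

#' Attempt a single T1 (neighbour-exchange) transition
#'
#' The junction is rotated 90 degrees about its midpoint with its length
#' preserved; the two cells that shared the junction lose it and the two
#' cells that met it only at an endpoint gain it. The move is accepted only
#' if it lowers [virtual_work()]. Junctions that are on the boundary, have
#' an endpoint of degree other than 3, or border a triangular cell are
#' skipped.
#'
#' @inheritParams virtual_work
#' @param junction_id Id of the junction to flip.
#' @return List with elements `tissue` (flipped or unchanged) and
#'   `accepted` (logical).
#' @export
t1_transition <- function(tis, junction_id, spec, params) {
  check_simulable(spec, params)
  fm <- mesh_data(tis)
  jrow <- match(junction_id, tis$junctions$id)
  if (is.na(jrow)) abort("unknown junction id", class = "epimech_key_error")
  loops <- lapply(tis$cells$vertex_loop, match, table = tis$vertices$id)
  trial <- t1_trial(fm, fm$pos, loops, jrow, spec, params)
  if (is.null(trial)) return(list(tissue = tis, accepted = FALSE))
  u_before <- u0_state(fm, flat_geometry(fm), spec, params)
  fm2 <- tryCatch(flat_from_loops(trial$pos, trial$loops),
                  error = function(e) NULL)
  if (is.null(fm2)) return(list(tissue = tis, accepted = FALSE))
  g2 <- flat_geometry(fm2, trial$pos)
  if (any(g2$A <= 0)) return(list(tissue = tis, accepted = FALSE))
  u_after <- u0_state(fm2, g2, spec, params)
  if (u_after >= u_before) return(list(tissue = tis, accepted = FALSE))
  list(tissue = state_to_tissue(trial$pos, trial$loops,
                                provenance = tis$meta$provenance),
       accepted = TRUE)
}

# Full relaxation engine on the flattened state.  The inner loop avoids
# trigonometric calls (sin 2theta and cos 2theta come straight from the edge
# vector) and accumulates tension and pressure contributions with a single
# rowsum per step over precompiled index vectors.
relax_engine <- function(pos, loops, spec, params, dt, t_end, t1_threshold,
                         trace_every = 50L, stop_tol = 0) {
  n_steps <- max(1L, round(t_end / dt))
  fm <- flat_from_loops(pos, loops)
  conventional <- spec$family == "conventional"
  co <- from_polar(spec, params)
  cf <- function(nm) if (nm %in% names(co)) unname(co[[nm]]) else 0
  a0 <- cf("lambda0"); as <- cf("lambda0p"); ac <- cf("lambda0pp")
  b0 <- cf("lambda1"); bs <- cf("lambda1p"); bc <- cf("lambda1pp")
  g0 <- cf("gamma0")
  kk <- params$k; A0 <- params$A0

  e1 <- e2 <- lv <- lvn <- lvp <- lc <- lj <- grp <- NULL
  nE <- nL <- 0L
  unpack <- function() {
    e1 <<- fm$ej[, 1]; e2 <<- fm$ej[, 2]
    lv <<- fm$loop_v; lc <<- fm$loop_cell; lj <<- fm$loop_j
    lvn <<- fm$loop_v[fm$loop_next]; lvp <<- fm$loop_v[fm$loop_prev]
    nE <<- fm$J; nL <<- length(lv)
    # groups: tension on e1, tension on e2, pressure on lv, pad with every
    # vertex so rowsum rows align with 1..V
    grp <<- c(e1, e2, lv, seq_len(fm$V))
  }
  unpack()
  x <- pos[, 1]; y <- pos[, 2]
  pad <- function(n) numeric(n)
  t1_count <- 0L
  # Rejected T1 attempts are cached: a short junction whose flip was refused
  # is re-tried only once it has shrunk by a further 0.5% or after 25 steps,
  # whichever comes first (its neighbourhood moves slowly between steps, so
  # the energy test cannot flip sign faster than that).  Any accepted flip
  # clears the cache.
  rej_len <- new.env(parent = emptyenv())
  rej_step <- new.env(parent = emptyenv())
  trace_t <- numeric(0); trace_u <- numeric(0)
  maxF <- Inf
  for (s in seq_len(n_steps)) {
    dx <- x[e2] - x[e1]; dy <- y[e2] - y[e1]
    l2 <- dx * dx + dy * dy
    l <- sqrt(l2)
    # T1 scan: one pass in ascending junction length, re-evaluating the
    # energy after each accepted flip
    if (t1_threshold > 0 && any(l < t1_threshold & !fm$boundary_j)) {
      pos <- cbind(x, y)
      cand <- which(l < t1_threshold & !fm$boundary_j)
      cand <- cand[order(l[cand])]
      # identify candidates by endpoint pair: accepted flips renumber rows
      cand_keys <- edge_key(fm$ej[cand, 1], fm$ej[cand, 2], fm$V)
      changed <- FALSE
      for (ci in seq_along(cand_keys)) {
        key <- cand_keys[ci]
        ks <- as.character(key)
        lnow <- l[cand[ci]]
        if (!is.null(rej_len[[ks]]) &&
            lnow > 0.995 * rej_len[[ks]] && s - rej_step[[ks]] < 25L) next
        jrow <- match(key, edge_key(fm$ej[, 1], fm$ej[, 2], fm$V))
        if (is.na(jrow)) next
        trial <- t1_trial(fm, pos, loops, jrow, spec, params)
        if (is.null(trial)) {
          rej_len[[ks]] <- lnow; rej_step[[ks]] <- s
          next
        }
        u_before <- local_u(loops, pos, trial$cells, spec, params)
        u_after <- local_u(trial$loops, trial$pos, trial$cells, spec, params)
        if (u_after < u_before) {
          fm2 <- tryCatch(flat_from_loops(trial$pos, trial$loops),
                          error = function(e) NULL)
          if (is.null(fm2)) next
          fm <- fm2; pos <- trial$pos; loops <- trial$loops
          t1_count <- t1_count + 1L
          changed <- TRUE
        } else {
          rej_len[[ks]] <- lnow; rej_step[[ks]] <- s
        }
      }
      if (changed) {
        rej_len <- new.env(parent = emptyenv())
        rej_step <- new.env(parent = emptyenv())
        unpack()
        x <- pos[, 1]; y <- pos[, 2]
        dx <- x[e2] - x[e1]; dy <- y[e2] - y[e1]
        l2 <- dx * dx + dy * dy
        l <- sqrt(l2)
      }
    }
    s2 <- 2 * dx * dy / l2
    c2 <- (dx * dx - dy * dy) / l2
    if (conventional) {
      perim <- rowsum(l[lj], lc)[, 1]
      P1 <- fm$jcells[, 1]; P2 <- fm$jcells[, 2]
      Ls <- ifelse(is.na(P1), 0, perim[P1]) + ifelse(is.na(P2), 0, perim[P2])
      Tj <- a0 + as * s2 + ac * c2 + g0 * Ls
    } else {
      Tj <- (a0 + as * s2 + ac * c2) - l * (b0 + bs * s2 + bc * c2)
    }
    til <- Tj / l
    tfx <- til * dx; tfy <- til * dy
    cross <- x[lv] * y[lvn] - x[lvn] * y[lv]
    A <- rowsum(cross, lc)[, 1] / 2
    Pc <- (-kk * (A - A0))[lc]
    pgx <- Pc * 0.5 * (y[lvn] - y[lvp])
    pgy <- Pc * 0.5 * (x[lvp] - x[lvn])
    Fs <- rowsum(cbind(c(tfx, -tfx, pgx, pad(fm$V)),
                       c(tfy, -tfy, pgy, pad(fm$V))), grp)
    x <- x + dt * Fs[, 1]
    y <- y + dt * Fs[, 2]
    if (s %% trace_every == 0L || s == n_steps) {
      if (!all(is.finite(x)) || !all(is.finite(y))) {
        abort(sprintf("numerical instability by step %d (non-finite coordinate)", s),
              class = "epimech_instability_error")
      }
      pos <- cbind(x, y)
      gg <- flat_geometry(fm, pos)
      trace_t <- c(trace_t, s * dt)
      trace_u <- c(trace_u, u0_state(fm, gg, spec, params))
      maxF <- max(abs(state_forces(fm, gg, spec, params, pos)))
      if (stop_tol > 0 && maxF < stop_tol) break
    }
  }
  list(pos = cbind(x, y), loops = loops, t1_count = t1_count,
       energy_trace = tibble(time = trace_t, U0 = trace_u),
       converged = maxF)
}

#' Relax a tissue under a cell vertex model
#'
#' Forward-Euler gradient descent of [virtual_work()]:
#' \eqn{x \leftarrow x + \Delta t\, f(x)}, with a T1 scan each step over
#' junctions shorter than `t1_threshold` (flips accepted only when they
#' lower the energy). Boundary vertices move freely under the same forces;
#' the exterior exerts no pressure.
#'
#' @inheritParams virtual_work
#' @param dt Time step.
#' @param t_end Total simulated time; the run always lasts `t_end / dt`
#'   steps unless `stop_tol` is set.
#' @param t1_threshold Junction length below which T1 transitions are
#'   attempted. Default `0.05 * sqrt(A0)`.
#' @param trace_every Record the energy every this many steps.
#' @param stop_tol If positive, stop early once the largest vertex force
#'   falls below this value (the fixed point reached is the same
#'   equilibrium the full run converges to).
#' @return A `sim_result`: list with `tissue`, `truth` (the generating
#'   [mech_params()]), `spec`, `energy_trace` (tibble `time`, `U0`),
#'   `t1_count`, and `converged` (final max |force|).
#' @export
relax_tissue <- function(tis, spec, params, dt = 0.1, t_end = 5000,
                         t1_threshold = 0.05 * sqrt(params$A0),
                         trace_every = 50L, stop_tol = 0) {
  check_simulable(spec, params)
  if (dt <= 0 || t_end < dt) abort("need dt > 0 and t_end >= dt",
                                   class = "epimech_config_error")
  v <- tis$vertices
  pos <- cbind(v$x, v$y)
  loops <- lapply(tis$cells$vertex_loop, match, table = v$id)
  res <- relax_engine(pos, loops, spec, params, dt, t_end, t1_threshold,
                      trace_every, stop_tol)
  out_tis <- state_to_tissue(res$pos, res$loops)
  out_tis$meta$A0 <- params$A0
  structure(list(tissue = out_tis,
                 truth = params, spec = spec,
                 energy_trace = res$energy_trace,
                 t1_count = res$t1_count, converged = res$converged),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s: %d cells, %d T1 transitions, final max|force| = %.3g\n",
              format(x$spec), nrow(x$tissue$cells), x$t1_count, x$converged))
  invisible(x)
}

#' Simulate a synthetic tissue with known ground truth
#'
#' Convenience pipeline: [generate_initial_tile()] then [relax_tissue()].
#' Deterministic given `seed`.
#'
#' @inheritParams relax_tissue
#' @inheritParams generate_initial_tile
#' @return A `sim_result` (see [relax_tissue()]).
#' @examples
#' \donttest{
#' spec <- model_spec("anisotropic_spring", "A")
#' par <- mech_params(lambda0 = 0.2, mu0 = 0.15, lambda1 = 0.03,
#'                    mu1 = 0.5, k = 1)
#' sim <- simulate_tissue(spec, par, n_rows = 4, n_cols = 4, t_end = 100,
#'                        seed = 1)
#' }
#' @export
simulate_tissue <- function(spec, params, n_rows = 20, n_cols = 20,
                            dt = 0.1, t_end = 5000,
                            t1_threshold = 0.05 * sqrt(params$A0),
                            seed = NULL, trace_every = 50L, stop_tol = 0) {
  tile <- generate_initial_tile(n_rows, n_cols, A0 = params$A0, seed = seed)
  tile$meta$A0 <- params$A0
  relax_tissue(tile, spec, params, dt = dt, t_end = t_end,
               t1_threshold = t1_threshold, trace_every = trace_every,
               stop_tol = stop_tol)
}
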
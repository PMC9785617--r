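# Steady creeping-flow solver for the connected dual-channel domain.
#
# Discretization: uniform staggered (MAC) grid; u on vertical faces, v on
# horizontal faces, p at cell centers. Viscous terms are second-order centered
# with the local phase viscosity (symmetric face/edge averages at phase
# interfaces), no-slip walls enter through mirror ghosts, inlets are Dirichlet
# velocity, outlets impose zero ghost pressure with zero streamwise velocity
# gradient. The convective term is dropped: channel Reynolds numbers are at
# most ~0.1 in this device, so the field solves the linear Stokes problem and
# scales exactly linearly with the inlet velocities.
#
# Solution strategy: the viscous block K is symmetric positive definite, so we
# factor it once with a supernodal Cholesky and run preconditioned CG on the
# pressure Schur complement G' K^-1 G, with the scaled pressure "mass" diagonal
# as preconditioner. This is exact (to CG tolerance) and fast even at ~5e5
# unknowns.

#' Plane-Poiseuille velocity profile
#'
#' Analytic fully developed laminar profile between two fixed parallel plates,
#' `u(y) = 6 u_mean y (h - y) / h^2`, which integrates back to `u_mean`.
#'
#' @param u_mean Mean (bulk) velocity (m/s).
#' @param h Plate separation (m).
#' @param y Distance from the lower plate (m); may be a vector in `[0, h]`.
#' @return Velocity (m/s) at `y`.
#' @examples
#' poiseuille_profile(1e-3, 1e-4, 0.5e-4)  # centerline: 1.5 * u_mean
#' @export
poiseuille_profile <- function(u_mean, h, y) {
  u_mean <- .q(u_mean, "u_mean"); h <- .q(h, "h")
  if (any(y < 0 | y > h)) abort("`y` must lie within [0, h].")
  6 * u_mean * y * (h - y) / h^2
}

#' Volumetric flow rate of a rectangular channel
#'
#' @param u_inlet Mean velocity (m/s or unit string).
#' @param width,height Cross-section dimensions (m or unit strings).
#' @return Flow rate in uL/min.
#' @examples
#' flow_rate("0.03 mm/s", "2000 um", "100 um")  # 0.36 uL/min
#' @export
flow_rate <- function(u_inlet, width, height) {
  u <- .q(u_inlet, "u_inlet"); w <- .q(width, "width"); h <- .q(height, "height")
  .check_pos(u, "u_inlet", strict = FALSE); .check_pos(w, "width"); .check_pos(h, "height")
  u * w * h * 1e9 * 60
}

# face masks and inlet values ------------------------------------------------

# cls codes: 0 solid, 1 air, 2 media, 3 pore
.fluid <- function(cl) cl > 0L

.inlet_values <- function(domain, u_air, u_media, profile) {
  ny <- domain$ny; dy <- domain$dy
  yc <- (seq_len(ny) - 0.5) * dy
  val <- numeric(ny)
  air_rows <- domain$cls[1, ] == 1L
  med_rows <- domain$cls[1, ] == 2L
  if (profile == "parabolic") {
    val[air_rows] <- poiseuille_profile(u_air, domain$geometry$h_air,
                                        yc[air_rows] - domain$y_mem_top)
    val[med_rows] <- poiseuille_profile(u_media, domain$geometry$h_media, yc[med_rows])
  } else {
    val[air_rows] <- u_air
    val[med_rows] <- u_media
  }
  val
}

#' Solve the steady flow field in the device
#'
#' Computes the steady incompressible creeping-flow velocity and pressure in
#' the connected air/media channels, with uniform (or fully developed) inlet
#' velocity, zero outlet pressure and no-slip on every solid boundary. Each
#' phase keeps its own density and viscosity; membrane pore slots carry the
#' bottom-phase (liquid) properties. When `shallow_depth` is set, the
#' depth-averaged Hele-Shaw drag `-12 mu u / depth^2` models a finite
#' out-of-plane depth.
#'
#' @param domain An [build_domain()] result.
#' @param fluid_top,fluid_bottom Phase properties of the upper (air) and lower
#'   (media) channel; pass media properties for `fluid_top` to model aqueous
#'   injection into the top channel.
#' @param u_top_inlet,u_bottom_inlet Inlet velocities (m/s or unit strings).
#' @param shallow_depth Optional out-of-plane depth (m); default taken from
#'   the geometry's `depth` field.
#' @param inlet_profile `"uniform"` plug inlet or `"parabolic"` fully
#'   developed inlet.
#' @param include_gravity Include the hydrostatic body force in the momentum
#'   balance (off by default: with constant-density phases it only shifts the
#'   pressure datum and would impose an artificial transmembrane head across
#'   the two stacked phases).
#' @param g Gravitational acceleration (m/s^2) when `include_gravity = TRUE`.
#' @param pore_flow `"closed"` (default) treats the pore slots as stagnant
#'   liquid for the flow solve: the air-liquid menisci pinned in the pores
#'   (capillary pressure far above the channel pressure head) block fluid
#'   exchange, while particles still pass through freely. `"open"` solves the
#'   fully connected problem with free fluid exchange through the slots.
#' @param tol Relative CG tolerance on the pressure Schur complement.
#' @param max_iter CG iteration budget.
#' @return An object of class `lc_flow`.
#' @export
solve_flow <- function(domain,
                       fluid_top = air_properties(),
                       fluid_bottom = media_properties(),
                       u_top_inlet = "0.3 mm/s", u_bottom_inlet = "0.3 mm/s",
                       shallow_depth = NULL,
                       inlet_profile = c("uniform", "parabolic"),
                       include_gravity = FALSE, g = 9.81,
                       pore_flow = c("closed", "open"),
                       tol = 1e-10, max_iter = 3000) {
  pore_flow <- match.arg(pore_flow)
  stopifnot(inherits(domain, "lc_domain"))
  inlet_profile <- match.arg(inlet_profile)
  u_top <- .q(u_top_inlet, "u_top_inlet")
  u_bot <- .q(u_bottom_inlet, "u_bottom_inlet")
  .check_pos(u_top, "u_top_inlet", strict = FALSE)
  .check_pos(u_bot, "u_bottom_inlet", strict = FALSE)
  if (is.null(shallow_depth)) shallow_depth <- domain$geometry$depth
  if (!is.null(shallow_depth)) .check_pos(.q(shallow_depth, "shallow_depth"), "shallow_depth")

  nx <- domain$nx; ny <- domain$ny; dx <- domain$dx; dy <- domain$dy
  cls <- domain$cls
  if (pore_flow == "closed") cls[cls == 3L] <- 0L  # stagnant slots
  if (nx < 3 || ny < 3) abort("Degenerate grid: too few cells.")

  mu_cell <- matrix(NA_real_, nx, ny)
  rho_cell <- matrix(NA_real_, nx, ny)
  mu_cell[cls == 1L] <- fluid_top$mu;  rho_cell[cls == 1L] <- fluid_top$rho
  mu_cell[cls >= 2L] <- fluid_bottom$mu; rho_cell[cls >= 2L] <- fluid_bottom$rho

  field_skeleton <- function(U, V, P, diag) {
    structure(list(
      domain = domain, u = U, v = V, p = P,
      dx = dx, dy = dy, nx = nx, ny = ny,
      fluid_top = fluid_top, fluid_bottom = fluid_bottom,
      u_top_inlet = u_top, u_bottom_inlet = u_bot,
      inlet_profile = inlet_profile, shallow_depth = shallow_depth,
      pore_flow = pore_flow, diagnostics = diag
    ), class = "lc_flow")
  }

  # trivial null forcing: identically zero field
  if (u_top == 0 && u_bot == 0 && !include_gravity) {
    U <- matrix(0, nx + 1, ny); V <- matrix(0, nx, ny + 1); P <- matrix(0, nx, ny)
    fl <- field_skeleton(U, V, P, list(cg_iters = 0L, cg_rel_residual = 0,
                                       max_div = 0, converged = TRUE))
    return(.finalize_field(fl))
  }

  inlet_u <- .inlet_values(domain, u_top, u_bot, inlet_profile)

  # --- face bookkeeping -----------------------------------------------------
  # u faces: (nx+1) x ny.  cell west = (i-1, j), cell east = (i, j).
  clW <- rbind(matrix(-1L, 1, ny), cls)            # -1: inlet boundary
  clE <- rbind(cls, matrix(-2L, 1, ny))            # -2: outlet boundary
  u_unknown <- (.fluid(clW) & .fluid(clE)) |
    (clW == -1L & FALSE) |                         # inlet faces are Dirichlet
    (clE == -2L & (clW == 1L | clW == 2L))         # outlet faces (not pore slots)
  u_known_val <- matrix(0, nx + 1, ny)
  inlet_face <- (clW == -1L) & .fluid(clE) & (clE != 3L)
  u_known_val[1, ] <- ifelse(inlet_face[1, ], inlet_u, 0)

  # v faces: nx x (ny+1).  cell south = (i, j-1), cell north = (i, j).
  clS <- cbind(matrix(-3L, nx, 1), cls)            # -3: exterior wall
  clN <- cbind(cls, matrix(-3L, nx, 1))
  v_unknown <- .fluid(clS) & .fluid(clN)

  p_fluid <- .fluid(cls)

  Uidx <- matrix(0L, nx + 1, ny); Uidx[u_unknown] <- seq_len(sum(u_unknown))
  n_u <- sum(u_unknown)
  Vidx <- matrix(0L, nx, ny + 1); Vidx[v_unknown] <- n_u + seq_len(sum(v_unknown))
  n_v <- sum(v_unknown)
  Pidx <- matrix(0L, nx, ny); Pidx[p_fluid] <- seq_len(sum(p_fluid))
  n_p <- sum(p_fluid)
  n_vel <- n_u + n_v

  # face viscosities (means of adjacent fluid cells; symmetric by construction)
  mu_pad <- matrix(NA_real_, nx + 2, ny + 2)
  mu_pad[2:(nx + 1), 2:(ny + 1)] <- mu_cell
  pairmean <- function(a, b) {
    out <- rowMeans(cbind(as.vector(a), as.vector(b)), na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    matrix(out, nrow(a), ncol(a))
  }
  muU <- pairmean(mu_pad[1:(nx + 1), 2:(ny + 1)], mu_pad[2:(nx + 2), 2:(ny + 1)]) # (nx+1) x ny
  muV <- pairmean(mu_pad[2:(nx + 1), 1:(ny + 1)], mu_pad[2:(nx + 1), 2:(ny + 2)]) # nx x (ny+1)

  ti <- vector("list", 32); tjj <- vector("list", 32); tx <- vector("list", 32); nt <- 0L
  gi <- vector("list", 16); gj <- vector("list", 16); gx <- vector("list", 16); ng <- 0L
  addK <- function(r, c, v) { nt <<- nt + 1L; ti[[nt]] <<- r; tjj[[nt]] <<- c; tx[[nt]] <<- v }
  addG <- function(r, c, v) { ng <<- ng + 1L; gi[[ng]] <<- r; gj[[ng]] <<- c; gx[[ng]] <<- v }
  f_rhs <- numeric(n_vel)
  g_rhs <- numeric(n_p)

  shallow_coef <- if (is.null(shallow_depth)) 0 else 12 / .q(shallow_depth, "shallow_depth")^2

  # --- u momentum -----------------------------------------------------------
  uf <- which(u_unknown, arr.ind = TRUE)
  ui <- uf[, 1]; uj <- uf[, 2]
  row <- Uidx[u_unknown]
  dg <- numeric(length(row))

  # x-neighbors through cells east (i, j) and west (i-1, j) of the face
  mu_e <- mu_pad[cbind(ui + 1, uj + 1)]  # cell (i, j)
  mu_w <- mu_pad[cbind(ui, uj + 1)]      # cell (i-1, j)
  # east neighbor u(i+1, j)
  has_e <- ui <= nx
  e_unk <- has_e & Uidx[cbind(pmin(ui + 1, nx + 1), uj)] > 0
  sel <- e_unk
  addK(row[sel], Uidx[cbind(ui[sel] + 1, uj[sel])], -mu_e[sel] / dx^2)
  dg <- dg + ifelse(has_e, mu_e / dx^2, 0)            # outlet face: zero-gradient ghost
  sel <- has_e & !e_unk                               # known east neighbor (wall = 0)
  # (value 0; nothing on rhs)
  # west neighbor u(i-1, j)
  w_unk <- Uidx[cbind(ui - 1, uj)] > 0
  sel <- w_unk
  addK(row[sel], Uidx[cbind(ui[sel] - 1, uj[sel])], -mu_w[sel] / dx^2)
  dg <- dg + mu_w / dx^2
  sel <- !w_unk                                       # known west neighbor (inlet or wall)
  f_rhs[row[sel]] <- f_rhs[row[sel]] + mu_w[sel] / dx^2 * u_known_val[cbind(ui[sel] - 1, uj[sel])]

  # y-neighbors u(i, j +/- 1); symmetric pair-mean viscosity at the edge
  for (sgn in c(1L, -1L)) {
    jn <- uj + sgn
    inside <- jn >= 1 & jn <= ny
    mu_n <- ifelse(inside, pairmean(matrix(muU[cbind(ui, uj)]),
                                    matrix(muU[cbind(ui, pmin(pmax(jn, 1), ny))]))[, 1],
                   muU[cbind(ui, uj)])
    mu_n[is.na(mu_n)] <- muU[cbind(ui, uj)][is.na(mu_n)]
    n_unk <- inside & Uidx[cbind(ui, pmin(pmax(jn, 1), ny))] > 0
    sel <- n_unk
    addK(row[sel], Uidx[cbind(ui[sel], jn[sel])], -mu_n[sel] / dy^2)
    # wall at the cell edge (outside domain, or neighbour face buried in solid):
    # mirror ghost doubles the coefficient; a fluid-adjacent Dirichlet face sits
    # a full dy away.
    nbr_cells_solid <- !inside |
      (!.fluid(clW[cbind(ui, pmin(pmax(jn, 1), ny))]) &
         !.fluid(clE[cbind(ui, pmin(pmax(jn, 1), ny))]))
    coef <- ifelse(n_unk, mu_n / dy^2, ifelse(nbr_cells_solid, 2 * mu_n / dy^2, mu_n / dy^2))
    dg <- dg + coef
    # known non-buried neighbours hold value 0 (walls); nothing on rhs
  }

  if (shallow_coef > 0) dg <- dg + shallow_coef * pairmean(matrix(mu_e), matrix(mu_w))[, 1]
  addK(row, row, dg)

  # pressure gradient: (p_E - p_W)/dx
  pe_in <- ui <= nx
  sel <- pe_in & Pidx[cbind(pmin(ui, nx), uj)] > 0
  addG(row[sel], Pidx[cbind(ui[sel], uj[sel])], rep(1 / dx, sum(sel)))
  sel <- Pidx[cbind(ui - 1, uj)] > 0
  addG(row[sel], Pidx[cbind(ui[sel] - 1, uj[sel])], rep(-1 / dx, sum(sel)))
  # outlet ghost pressure is 0: contributes nothing

  # --- v momentum -----------------------------------------------------------
  vf <- which(v_unknown, arr.ind = TRUE)
  vi <- vf[, 1]; vj <- vf[, 2]
  row <- Vidx[v_unknown]
  dg <- numeric(length(row))

  mu_n <- mu_pad[cbind(vi + 1, vj + 1)]  # cell (i, j)
  mu_s <- mu_pad[cbind(vi + 1, vj)]      # cell (i, j-1)
  # north neighbor v(i, j+1)
  has_n <- vj <= ny
  n_unk <- has_n & Vidx[cbind(vi, pmin(vj + 1, ny + 1))] > 0
  sel <- n_unk
  addK(row[sel], Vidx[cbind(vi[sel], vj[sel] + 1)], -mu_n[sel] / dy^2)
  dg <- dg + mu_n / dy^2                 # known neighbours are walls at distance dy
  # south neighbor v(i, j-1)
  s_unk <- Vidx[cbind(vi, vj - 1)] > 0
  sel <- s_unk
  addK(row[sel], Vidx[cbind(vi[sel], vj[sel] - 1)], -mu_s[sel] / dy^2)
  dg <- dg + mu_s / dy^2

  # x-neighbors v(i +/- 1, j)
  for (sgn in c(1L, -1L)) {
    im <- vi + sgn
    inside <- im >= 1 & im <= nx
    mu_x <- ifelse(inside, pairmean(matrix(muV[cbind(vi, vj)]),
                                    matrix(muV[cbind(pmin(pmax(im, 1), nx), vj)]))[, 1],
                   muV[cbind(vi, vj)])
    mu_x[is.na(mu_x)] <- muV[cbind(vi, vj)][is.na(mu_x)]
    x_unk <- inside & Vidx[cbind(pmin(pmax(im, 1), nx), vj)] > 0
    sel <- x_unk
    addK(row[sel], Vidx[cbind(im[sel], vj[sel])], -mu_x[sel] / dx^2)
    nbr_cells_solid <- inside &
      (!.fluid(clS[cbind(pmin(pmax(im, 1), nx), vj)]) &
         !.fluid(clN[cbind(pmin(pmax(im, 1), nx), vj)]))
    at_inlet <- !inside & sgn == -1L       # v = 0 on the inlet plane (dx/2 away)
    at_outlet <- !inside & sgn == 1L       # zero-gradient ghost
    coef <- ifelse(x_unk, mu_x / dx^2,
                   ifelse(nbr_cells_solid | at_inlet, 2 * mu_x / dx^2,
                          ifelse(at_outlet, 0, mu_x / dx^2)))
    dg <- dg + coef
  }

  if (shallow_coef > 0) dg <- dg + shallow_coef * pairmean(matrix(mu_n), matrix(mu_s))[, 1]
  addK(row, row, dg)

  if (include_gravity) {
    rho_f <- pairmean(matrix(rho_cell[cbind(vi, pmin(vj, ny))]),
                      matrix(rho_cell[cbind(vi, pmax(vj - 1, 1))]))[, 1]
    f_rhs[row] <- f_rhs[row] - rho_f * .q(g, "g")
  }

  # pressure gradient: (p_N - p_S)/dy
  sel <- vj <= ny & Pidx[cbind(vi, pmin(vj, ny))] > 0
  addG(row[sel], Pidx[cbind(vi[sel], vj[sel])], rep(1 / dy, sum(sel)))
  sel <- Pidx[cbind(vi, vj - 1)] > 0
  addG(row[sel], Pidx[cbind(vi[sel], vj[sel] - 1)], rep(-1 / dy, sum(sel)))

  # --- continuity rhs from known faces -------------------------------------
  pf <- which(p_fluid, arr.ind = TRUE)
  pi_ <- pf[, 1]; pj <- pf[, 2]
  prow <- Pidx[p_fluid]
  # (u_E - u_W)/dx + (v_N - v_S)/dy = 0; known faces move to the rhs
  uW_kn <- Uidx[cbind(pi_, pj)] == 0
  g_rhs[prow[uW_kn]] <- g_rhs[prow[uW_kn]] + u_known_val[cbind(pi_[uW_kn], pj[uW_kn])] / dx
  # (known east/north/south faces are all zero-valued walls)

  K <- Matrix::sparseMatrix(i = unlist(ti[seq_len(nt)]), j = unlist(tjj[seq_len(nt)]),
                            x = unlist(tx[seq_len(nt)]), dims = c(n_vel, n_vel))
  G <- Matrix::sparseMatrix(i = unlist(gi[seq_len(ng)]), j = unlist(gj[seq_len(ng)]),
                            x = unlist(gx[seq_len(ng)]), dims = c(n_vel, n_p))

  Ch <- Matrix::Cholesky(K, LDL = FALSE, super = TRUE)
  ksolve <- function(b) as.numeric(Matrix::solve(Ch, b))

  # Schur complement CG:  (G' K^-1 G) p = G' K^-1 f + g, preconditioned by
  # the viscosity-scaled pressure "mass" diagonal. The air/media viscosity
  # contrast costs extra iterations (the air block's pressures are ~40x
  # smaller, so the global relative tolerance forces further reduction
  # there), but each iteration is only two triangular solves on K.
  rhsS <- as.numeric(Matrix::crossprod(G, ksolve(f_rhs))) + g_rhs
  mu_p <- mu_cell[p_fluid]
  psolve <- function(b) b * dx * dy / mu_p
  p_sol <- numeric(n_p)
  r <- rhsS
  nrm0 <- sqrt(sum(r^2))
  it <- 0L
  if (nrm0 > 0) {
    z <- psolve(r); rho_cg <- sum(r * z); pdir <- z
    for (it in seq_len(max_iter)) {
      Sp <- as.numeric(Matrix::crossprod(G, ksolve(as.numeric(G %*% pdir))))
      alpha <- rho_cg / sum(pdir * Sp)
      p_sol <- p_sol + alpha * pdir
      r <- r - alpha * Sp
      if (sqrt(sum(r^2)) <= tol * nrm0) break
      z <- psolve(r)
      rho_new <- sum(r * z); beta <- rho_new / rho_cg; rho_cg <- rho_new
      pdir <- z + beta * pdir
    }
  }
  rel_res <- if (nrm0 > 0) sqrt(sum(r^2)) / nrm0 else 0
  if (rel_res > sqrt(tol)) {
    abort(sprintf(paste0("Flow solve did not converge: CG relative residual %.2e ",
                         "after %d iterations."), rel_res, it))
  }
  uv <- ksolve(f_rhs - as.numeric(G %*% p_sol))

  U <- u_known_val
  U[u_unknown] <- uv[seq_len(n_u)]
  V <- matrix(0, nx, ny + 1)
  V[v_unknown] <- uv[n_u + seq_len(n_v)]
  P <- matrix(0, nx, ny)
  P[p_fluid] <- p_sol

  fl <- field_skeleton(U, V, P, list(cg_iters = it, cg_rel_residual = rel_res,
                                     max_div = NA_real_, converged = TRUE))
  fl <- .finalize_field(fl)
  fl$diagnostics$max_div <- max_divergence(fl)
  fl
}

# ghost-filled copies of the velocity arrays so that bilinear sampling honours
# no-slip exactly on walls that coincide with cell edges
.finalize_field <- function(field) {
  domain <- field$domain
  nx <- field$nx; ny <- field$ny
  cls <- domain$cls
  U <- field$u; V <- field$v

  # u lattice: mark faces adjacent to at least one fluid cell
  clW <- rbind(matrix(0L, 1, ny), cls)
  clE <- rbind(cls, matrix(0L, 1, ny))
  MU <- .fluid(clW) | .fluid(clE)
  Ug <- U
  buried <- !MU
  # mirror from above / below where a fluid-adjacent face sits next door
  for (j in seq_len(ny)) {
    idx <- which(buried[, j])
    if (!length(idx)) next
    if (j < ny) {
      up <- idx[MU[idx, j + 1]]
      Ug[cbind(up, j)] <- -U[cbind(up, j + 1)]
      idx <- setdiff(idx, up)
    }
    if (j > 1 && length(idx)) {
      dn <- idx[MU[idx, j - 1]]
      Ug[cbind(dn, j)] <- -U[cbind(dn, j - 1)]
    }
  }
  u_pad <- cbind(-Ug[, 1], Ug, -Ug[, ny])   # exterior bottom/top mirror rows

  clS <- cbind(matrix(0L, nx, 1), cls)
  clN <- cbind(cls, matrix(0L, nx, 1))
  MV <- .fluid(clS) | .fluid(clN)
  Vg <- V
  buried <- !MV
  for (j in seq_len(ny + 1)) {
    idx <- which(buried[, j])
    if (!length(idx)) next
    right <- idx[idx < nx]
    right <- right[MV[right + 1, j]]
    Vg[cbind(right, j)] <- -V[cbind(right + 1, j)]
    idx <- setdiff(idx, right)
    left <- idx[idx > 1]
    left <- left[MV[left - 1, j]]
    if (length(left)) Vg[cbind(left, j)] <- -V[cbind(left - 1, j)]
  }
  v_pad <- rbind(-Vg[1, ], Vg, Vg[nx, ])    # inlet mirror, outlet zero-gradient

  field$u_pad <- u_pad
  field$v_pad <- v_pad
  field
}

#' Maximum discrete divergence of a flow field
#'
#' @param field An [solve_flow()] result.
#' @return Maximum absolute cell divergence (1/s) over fluid cells.
#' @export
max_divergence <- function(field) {
  stopifnot(inherits(field, "lc_flow"))
  nx <- field$nx; ny <- field$ny
  div <- (field$u[2:(nx + 1), , drop = FALSE] - field$u[1:nx, , drop = FALSE]) / field$dx +
    (field$v[, 2:(ny + 1), drop = FALSE] - field$v[, 1:ny, drop = FALSE]) / field$dy
  max(abs(div[.fluid(field$domain$cls)]))
}

#' Sample the velocity field at arbitrary points
#'
#' Continuous bilinear interpolation on the staggered lattice. Nodal values
#' are reproduced exactly and the interpolant vanishes on no-slip walls.
#'
#' @param field An [solve_flow()] result.
#' @param x,y Query coordinates (m); vectors of equal length.
#' @return A tibble with columns `x`, `y`, `u`, `v`.
#' @export
sample_velocity <- function(field, x, y) {
  stopifnot(inherits(field, "lc_flow"))
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  domain <- field$domain
  eps <- 1e-12
  inside <- x >= -eps & x <= domain$geometry$l + eps & y >= -eps & y <= domain$y_top + eps
  if (!all(inside)) abort("Velocity query outside the domain bounding box.")
  reg <- .region_of(domain, x, y)
  if (any(reg == "solid")) abort("Velocity query inside the solid membrane.")
  uv <- sample_velocity_cpp(field$u_pad, field$v_pad, field$dx, field$dy,
                            field$nx, field$ny, x, y)
  tibble(x = x, y = y, u = uv[[1]], v = uv[[2]])
}

# region classification of points against the exact (not gridded) geometry
.region_of <- function(domain, x, y) {
  out <- rep("solid", length(x))
  out[y >= domain$y_mem_top & y <= domain$y_top] <- "air"      # wall plane: air side
  out[y <= domain$y_mem_bot & y >= 0] <- "media"
  in_band <- y > domain$y_mem_bot & y < domain$y_mem_top
  if (any(in_band) && nrow(domain$pores) > 0) {
    for (k in seq_len(nrow(domain$pores))) {
      sel <- in_band & x >= domain$pores$x0[k] & x <= domain$pores$x1[k]
      out[sel] <- "pore"
    }
  }
  out
}

#' Net volumetric flux through the membrane pores
#'
#' Integrates the vertical velocity across the pore mouths at the
#' membrane-top plane (positive = upward, per unit depth, m^2/s). Zero by
#' construction when the field was solved with `pore_flow = "closed"`.
#'
#' @param field An [solve_flow()] result.
#' @return Net flux (m^2/s).
#' @export
pore_flux <- function(field) {
  stopifnot(inherits(field, "lc_flow"))
  domain <- field$domain
  if (nrow(domain$pores) == 0) return(0)
  j_top <- domain$n_media + domain$n_mem + 1L  # v-face row at the membrane top
  xc <- (seq_len(field$nx) - 0.5) * field$dx
  in_pore <- rep(FALSE, field$nx)
  for (k in seq_len(nrow(domain$pores))) {
    in_pore <- in_pore | (xc > domain$pores$x0[k] & xc < domain$pores$x1[k])
  }
  sum(field$v[in_pore, j_top]) * field$dx
}

#' Channel flux balance
#'
#' Inlet, outlet and pore fluxes per channel (per unit depth, m^2/s); for a
#' converged incompressible solve the imbalance is at the solver tolerance.
#'
#' @param field An [solve_flow()] result.
#' @return A tibble with one row per channel.
#' @export
flux_balance <- function(field) {
  stopifnot(inherits(field, "lc_flow"))
  domain <- field$domain
  air_rows <- domain$cls[1, ] == 1L
  med_rows <- domain$cls[1, ] == 2L
  dy <- field$dy
  qp <- pore_flux(field)
  tibble(
    channel = c("air", "media"),
    inlet = c(sum(field$u[1, air_rows]) * dy, sum(field$u[1, med_rows]) * dy),
    outlet = c(sum(field$u[field$nx + 1, air_rows]) * dy,
               sum(field$u[field$nx + 1, med_rows]) * dy),
    pore = c(-qp, qp)   # flux delivered *into* the channel through the pores
  )
}

#' Analytic single-channel flow field
#'
#' Builds a flow field object carrying the exact plane-Poiseuille (or plug)
#' profile in the air channel of an impermeable-membrane device. Useful for
#' verification runs against parallel-plate transport references where a
#' numerical flow solve is unnecessary.
#'
#' @param h Channel height (m).
#' @param l Channel length (m).
#' @param u_mean Mean velocity (m/s).
#' @param fluid Carrier phase properties.
#' @param profile `"parabolic"` or `"uniform"`.
#' @param n_cells Vertical resolution of the stored lattice.
#' @return An `lc_flow` object whose domain is a single channel above a
#'   sticky floor (the membrane top of an impermeable device).
#' @export
channel_field <- function(h, l, u_mean, fluid = air_properties(),
                          profile = c("parabolic", "uniform"), n_cells = 50) {
  profile <- match.arg(profile)
  h <- .q(h, "h"); l <- .q(l, "l"); u_mean <- .q(u_mean, "u_mean")
  cell <- h / n_cells
  geom <- channel_geometry(h_air = h, h_media = 4 * cell, l = l, b = cell,
                           d = 0, p2p = cell)
  domain <- build_domain(geom, cell = cell)
  nx <- domain$nx; ny <- domain$ny
  yc <- (seq_len(ny) - 0.5) * domain$dy
  uprof <- numeric(ny)
  air_rows <- domain$cls[1, ] == 1L
  if (profile == "parabolic") {
    uprof[air_rows] <- poiseuille_profile(u_mean, h, yc[air_rows] - domain$y_mem_top)
  } else {
    uprof[air_rows] <- u_mean
  }
  U <- matrix(rep(uprof, each = nx + 1), nx + 1, ny)
  V <- matrix(0, nx, ny + 1)
  P <- matrix(0, nx, ny)
  fl <- structure(list(
    domain = domain, u = U, v = V, p = P,
    dx = domain$dx, dy = domain$dy, nx = nx, ny = ny,
    fluid_top = fluid, fluid_bottom = fluid,
    u_top_inlet = u_mean, u_bottom_inlet = 0,
    inlet_profile = profile, shallow_depth = NULL,
    diagnostics = list(cg_iters = 0L, cg_rel_residual = 0, max_div = 0,
                       converged = TRUE, analytic = TRUE)
  ), class = "lc_flow")
  .finalize_field(fl)
}

#' @export
print.lc_flow <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<lc_flow> %d x %d cells; inlets %.3g / %.3g mm/s; CG %d iters (rel res %.1e)\n",
              x$nx, x$ny, x$u_top_inlet * 1e3, x$u_bottom_inlet * 1e3,
              d$cg_iters, d$cg_rel_residual))
  invisible(x)
}

#' Cross-channel velocity profile for plotting or export
#'
#' @param field An [solve_flow()] result.
#' @param x Streamwise station (m).
#' @return A tibble with `y`, `u`, `v` down the full device height.
#' @export
velocity_profile <- function(field, x) {
  stopifnot(inherits(field, "lc_flow"))
  x <- .q(x, "x")
  domain <- field$domain
  yc <- (seq_len(field$ny) - 0.5) * field$dy
  reg <- .region_of(domain, rep(x, length(yc)), yc)
  keep <- reg != "solid"
  sample_velocity(field, rep(x, sum(keep)), yc[keep])
}
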
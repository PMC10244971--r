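# Reference implementations of the node-node interaction potentials.
#
# Three functional forms cover all six interactions:
#   Morse      E(r) = U exp(-r/xi) - V exp(-r/gamma)        (soft core)
#   spring     E(r) = k/2 (r - l_eq)^2
#   bending    E(theta) = k/2 (theta - theta_eq)^2          (angle at the
#                                                            middle node)
# r is the Euclidean distance between the two nodes. The Morse form is
# finite at r = 0 and, when U/xi = V/gamma, its derivative vanishes there,
# so the force is continuous through coincident nodes. These functions are
# the documented surface and the oracle route for the compiled kernel.

#' Soft-core Morse potential energy
#'
#' `U exp(-r/xi) - V exp(-r/gamma)`, finite for all separations. Used for
#' turgor pressure (wall vs own cytoplasm), volume exclusion between walls of
#' different cells, and cytoplasmic pressure (cytoplasm vs own cytoplasm).
#'
#' @param r separation (µm), >= 0; vectorised.
#' @param U,V energy coefficients (µN·µm), positive.
#' @param xi,gamma decay lengths (µm), positive.
#' @return energy (µN·µm).
#' @export
morse_energy <- function(r, U, V, xi, gamma) {
  if (any(r < 0)) stop("domain error: negative separation")
  stopifnot(U > 0, V > 0, xi > 0, gamma > 0)
  U * exp(-r / xi) - V * exp(-r / gamma)
}

# dE/dr of the Morse form
morse_dEdr <- function(r, U, V, xi, gamma) {
  -(U / xi) * exp(-r / xi) + (V / gamma) * exp(-r / gamma)
}

#' Morse force on the node at `x`
#'
#' Returns `-dE/dr * (x - y)/|x - y|`. At coincidence (`x == y`) the force is
#' the zero vector; if the parameters violate the continuity constraint
#' `U/xi == V/gamma` there, a warning is raised because the force is then
#' discontinuous through zero separation.
#'
#' @param x,y 2-vectors, node positions.
#' @param U,V,xi,gamma Morse coefficients as in [morse_energy()].
#' @return 2-vector force on `x` (µN); the force on `y` is its negative.
#' @export
morse_force <- function(x, y, U, V, xi, gamma) {
  d <- x - y
  r <- sqrt(sum(d * d))
  if (r == 0) {
    if (abs(U / xi - V / gamma) > 1e-9 * max(U / xi, V / gamma))
      warning("Morse force discontinuous at zero separation (U/xi != V/gamma)")
    return(c(0, 0))
  }
  -morse_dEdr(r, U, V, xi, gamma) * d / r
}

#' Linear spring energy
#' @param r separation (µm).
#' @param k stiffness (µN/µm), > 0.
#' @param l_eq rest length (µm), >= 0.
#' @return energy (µN·µm).
#' @export
spring_energy <- function(r, k, l_eq) {
  stopifnot(k > 0, l_eq >= 0)
  0.5 * k * (r - l_eq)^2
}

#' Linear spring force on the node at `x`
#'
#' Restoring force of magnitude `k (r - l_eq)` along the pair axis. At exact
#' coincidence with a nonzero rest length the direction is undefined: the
#' zero vector is returned with a degeneracy warning.
#'
#' @param x,y 2-vectors.
#' @param k,l_eq as in [spring_energy()].
#' @return 2-vector force on `x` (µN).
#' @export
linear_spring_force <- function(x, y, k, l_eq) {
  d <- x - y
  r <- sqrt(sum(d * d))
  if (r == 0) {
    if (l_eq > 0) warning("degenerate spring: coincident nodes with l_eq > 0")
    return(c(0, 0))
  }
  -k * (r - l_eq) * d / r
}

#' Bending (angle) spring energy
#' @param y,x,z 2-vectors; the penalised angle is at `x`, between legs to `y`
#'   and `z`.
#' @param k_bend stiffness (µN·µm/rad^2).
#' @param theta_eq equilibrium angle (rad); `pi` for a straight wall.
#' @return energy (µN·µm).
#' @export
bending_energy <- function(y, x, z, k_bend, theta_eq = pi) {
  u <- y - x; v <- z - x
  lu <- sqrt(sum(u * u)); lv <- sqrt(sum(v * v))
  if (lu == 0 || lv == 0) stop("bending angle undefined: zero-length leg")
  ct <- max(-1, min(1, sum(u * v) / (lu * lv)))
  0.5 * k_bend * (acos(ct) - theta_eq)^2
}

#' Bending spring forces on the angle triplet
#'
#' Gradient of [bending_energy()] with respect to all three positions. The
#' three returned forces sum to the zero vector and exert zero net torque
#' about `x`.
#'
#' @inheritParams bending_energy
#' @return list with 2-vector components `on_y`, `on_x`, `on_z`.
#' @export
bending_force <- function(y, x, z, k_bend, theta_eq = pi) {
  u <- y - x; v <- z - x
  lu <- sqrt(sum(u * u)); lv <- sqrt(sum(v * v))
  if (lu == 0 || lv == 0) stop("bending angle undefined: zero-length leg")
  uh <- u / lu; vh <- v / lv
  ct <- max(-1, min(1, sum(uh * vh)))
  st <- sqrt(max(0, 1 - ct * ct))
  theta <- acos(ct)
  if (st < 1e-9) {
    # straight (or folded) configuration: gradient direction degenerates;
    # with theta_eq = pi and theta = pi the force is exactly zero
    if (abs(theta - theta_eq) < 1e-9) {
      z2 <- c(0, 0)
      return(list(on_y = z2, on_x = z2, on_z = z2))
    }
    # deterministic perpendicular push out of the degenerate line
    perp <- c(-uh[2], uh[1])
    mag <- k_bend * (theta - theta_eq)
    fy <- mag * perp / lu
    fz <- -mag * perp / lv
    return(list(on_y = fy, on_x = -(fy + fz), on_z = fz))
  }
  # d(theta)/dy and d(theta)/dz; d(theta)/dx = -(sum)
  dth_dy <- (ct * uh - vh) / (lu * st)
  dth_dz <- (ct * vh - uh) / (lv * st)
  coef <- -k_bend * (theta - theta_eq)
  fy <- coef * dth_dy
  fz <- coef * dth_dz
  list(on_y = fy, on_x = -(fy + fz), on_z = fz)
}
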
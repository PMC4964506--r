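# In-code fixtures and independent oracles shared across the suite.

# minimal water-only topology: n waters (O,H,H), all in one pore label
water_topology <- function(n, pore = "A") {
  rows <- lapply(seq_len(n), function(i) data.frame(
    name = c("OH2", "H1", "H2"), residue_name = "HOH",
    residue_id = i, pore_label = pore,
    mass = c(15.9994, 1.008, 1.008), charge = c(-0.834, 0.417, 0.417),
    is_heavy = c(TRUE, FALSE, FALSE), is_water = TRUE,
    stringsAsFactors = FALSE))
  atoms <- do.call(rbind, rows)
  aq_topology(cbind(atom_id = seq_len(nrow(atoms)) - 1L, atoms))
}

# trajectory window from per-water oxygen paths: z [nf x n], optional xy
window_from_z <- function(z, xy = NULL, dt = 0.01, box = c(Inf, Inf, Inf),
                          origin = c(0, 0, 0), unwrapped = TRUE) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  nf <- nrow(z); n <- ncol(z)
  if (is.null(xy)) xy <- matrix(0, n, 2)
  co <- array(0, dim = c(nf, 3 * n, 3))
  oi <- 3 * (seq_len(n) - 1) + 1
  co[, oi, 1] <- matrix(xy[, 1], nf, n, byrow = TRUE)
  co[, oi, 2] <- matrix(xy[, 2], nf, n, byrow = TRUE)
  co[, oi, 3] <- z
  for (h in 1:2) {
    co[, oi + h, 1] <- co[, oi, 1] + 0.3 * h
    co[, oi + h, 2] <- co[, oi, 2]
    co[, oi + h, 3] <- co[, oi, 3]
  }
  trajectory_window((seq_len(nf) - 1) * dt, co, unwrapped = unwrapped,
                    box = box, origin = origin)
}

# two-point dumbbell residue topology for dipole closed forms
dumbbell_topology <- function(q = 1, mass = c(12, 12), resname = "SER") {
  aq_topology(data.frame(
    atom_id = 0:1, name = c("C1", "C2"), residue_name = resname,
    residue_id = 1L, pore_label = "A", mass = mass, charge = c(q, -q),
    is_heavy = TRUE, is_water = FALSE, stringsAsFactors = FALSE))
}

default_region <- function(pore = "A", center = c(0, 0), radius = 4,
                           z = c(-10, 10)) {
  channel_region(pore, center, radius, z[1], z[2])
}

# --- independent distribution oracles (numerical quadrature of closed-form
# densities written from the Gamma-function definitions; no pt/pf calls) ---

t_density <- function(x, nu) {
  exp(lgamma((nu + 1) / 2) - lgamma(nu / 2)) / sqrt(nu * pi) *
    (1 + x^2 / nu)^(-(nu + 1) / 2)
}

# one-tailed upper p-value P(T > t)
t_upper_oracle <- function(t, nu) {
  if (!is.finite(t)) return(if (t > 0) 0 else 1)
  stats::integrate(t_density, lower = t, upper = Inf, nu = nu,
                   rel.tol = 1e-10)$value
}

f_density <- function(x, d1, d2) {
  exp(lgamma((d1 + d2) / 2) - lgamma(d1 / 2) - lgamma(d2 / 2)) *
    (d1 / d2)^(d1 / 2) * x^(d1 / 2 - 1) *
    (1 + d1 * x / d2)^(-(d1 + d2) / 2)
}

f_upper_oracle <- function(f, d1, d2) {
  if (!is.finite(f)) return(0)
  stats::integrate(f_density, lower = f, upper = Inf, d1 = d1, d2 = d2,
                   rel.tol = 1e-10)$value
}
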
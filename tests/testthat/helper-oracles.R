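# Analytic helpers and independent oracles used across tests.

# area of a disc of radius r lying above a horizontal line a distance h
# below its center (h >= 0; h >= r gives the full disc)
disc_area_above_line <- function(r, h) {
  if (h >= r) return(pi * r^2)
  seg <- r^2 * acos(h / r) - h * sqrt(r^2 - h^2) # minor segment below line
  pi * r^2 - seg
}

# lens (intersection) area of two discs with center distance d
lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

# analytic lumen area of the default-style geometry: channel slab plus the
# dome union above the upper wall (valid when dome 2 and the lens both lie
# entirely above the wall line, which the caller must ensure)
analytic_lumen_area <- function(p, Lx) {
  area <- Lx * p$channel_width
  if (p$dome1_radius > 0) {
    h1 <- sqrt(p$dome1_radius^2 - (p$neck_width / 2)^2)
    area <- area + disc_area_above_line(p$dome1_radius, h1)
    if (p$dome2_radius > 0) {
      area <- area + pi * p$dome2_radius^2 -
        lens_area(p$dome1_radius, p$dome2_radius, p$dome_offset)
    }
  }
  area
}

# analytic perimeter of the capped lumen boundary (channel open ends
# capped): bottom wall + two end caps + upper wall minus neck chord +
# outer arcs of the two domes
analytic_lumen_perimeter <- function(p, Lx) {
  per <- Lx + 2 * p$channel_width + (Lx - p$neck_width)
  if (p$dome1_radius > 0) {
    th_neck <- 2 * asin((p$neck_width / 2) / p$dome1_radius)
    if (p$dome2_radius > 0) {
      d <- p$dome_offset; r1 <- p$dome1_radius; r2 <- p$dome2_radius
      th1 <- 2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
      th2 <- 2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
      per <- per + r1 * (2 * pi - th_neck - th1) + r2 * (2 * pi - th2)
    } else {
      per <- per + p$dome1_radius * (2 * pi - th_neck)
    }
  }
  per
}

# brute-force OSI / TAWSS quadrature for a single series: plain loop over
# periodic trapezoid panels, no vectorization shared with the package
osi_brute <- function(t, tau, period) {
  n <- length(t)
  ti <- c(t, t[1] + period)
  taui <- c(tau, tau[1])
  int_s <- 0; int_a <- 0
  for (k in seq_len(n)) {
    w <- ti[k + 1] - ti[k]
    int_s <- int_s + w * (taui[k] + taui[k + 1]) / 2
    int_a <- int_a + w * (abs(taui[k]) + abs(taui[k + 1])) / 2
  }
  if (int_a == 0) return(list(osi = 0, tawss = 0, mean = 0))
  list(osi = 0.5 * (1 - abs(int_s) / int_a), tawss = int_a / period,
       mean = int_s / period)
}

# a minimal synthetic flow snapshot with prescribed uniform velocity
uniform_snapshot <- function(geometry, u = 0, v = 0) {
  structure(list(uc = matrix(u, geometry$nx, geometry$ny),
                 vc = matrix(v, geometry$nx, geometry$ny),
                 p = matrix(0, geometry$nx, geometry$ny),
                 mu = matrix(0.0035, geometry$nx, geometry$ny),
                 t = 0, dx = geometry$dx), class = "flow_snapshot")
}

# hand-built index report for pipeline tests (no solve involved)
fake_report <- function(label, H, porosity, scale = 1, fingerprint = "fp") {
  ph <- pi * c(max_accel = 0.11, peak_sys = 0.23, max_decel = 0.31,
               early_dia = 0.43)
  structure(list(label = label, H = H, porosity = porosity,
                 s = seq(0, 1, length.out = 5),
                 tawss = rep(scale, 5), osi = rep(0.1, 5),
                 wall_valid = rep(TRUE, 5), in_view = rep(TRUE, 5),
                 max_wss = scale * ph, wall_pressure_max = scale * 10 * ph,
                 neck_avg_velocity = scale * 0.1 * ph,
                 max_osi_phase = pmin(0.1 * scale * ph, 0.5),
                 max_osi = 0.4, tau_floor = 0.01 * scale,
                 ke_sac_mean = scale * 1e-6,
                 frac_invalid = 0, phase_times = ph / 10,
                 cycle_peak_wss = c(1, 1, 1) * scale,
                 fingerprint = fingerprint,
                 field_of_view = "test", schema_version = "1.0"),
            class = "index_report")
}
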
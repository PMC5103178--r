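# Unit conventions, shared package-wide:
#   concentrations in uM (1 mg/L O2 = 31.25 uM), flow in uL/h at interfaces
#   and L/s internally, sOUR in amol cell^-1 s^-1 (1 mol = 1e18 amol).
UM_PER_MG_L <- 31.25
SENSOR_MAX_UM <- 45 * UM_PER_MG_L # optical sensor range 0-45 mg/L
AMOL_PER_MOL <- 1e18

flow_L_s <- function(q_uL_h) q_uL_h * 1e-6 / 3600

# Inlet-outlet differential (uM) produced by X cells at a given sOUR.
sour_delta_uM <- function(sour_amol, X, q_uL_h) {
  sour_amol / AMOL_PER_MOL * X / flow_L_s(q_uL_h) * 1e6
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic sub-stream seeds so partial re-runs of one component do not
# perturb another component's draws.
substream_seed <- function(seed, component) {
  offsets <- c(growth = 11L, render = 23L, sensors = 37L, spikes = 41L,
               classifier = 53L, assay = 67L)
  stopifnot(component %in% names(offsets))
  (as.integer(seed) * 1009L + offsets[[component]]) %% 2147483587L
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("'%s' must be finite", what), call. = FALSE)
  invisible(x)
}

first_order_filter <- function(x, t_h, tau_min) {
  if (tau_min <= 0 || length(x) < 2) return(x)
  y <- x
  tau_h <- tau_min / 60
  for (i in 2:length(x)) {
    a <- 1 - exp(-(t_h[i] - t_h[i - 1]) / tau_h)
    y[i] <- y[i - 1] + a * (x[i] - y[i - 1])
  }
  y
}
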
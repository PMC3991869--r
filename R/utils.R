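# internal helpers shared across modules

.vg_stop <- function(...) stop(..., call. = FALSE)

.vg_check <- function(cond, msg) {
  if (!isTRUE(cond)) .vg_stop(msg)
}

# cosine half-wave ease from v0 at t = 0 to v1 at t = w; zero slope at both ends
.ease_cos <- function(t, v0, v1, w) {
  u <- pmin(pmax(t / w, 0), 1)
  v0 + (v1 - v0) * (1 - cos(pi * u)) / 2
}

# cubic Hermite on [0, dt] with endpoint values v0, v1 and slopes m0, m1
.hermite <- function(t, dt, v0, v1, m0, m1) {
  u <- t / dt
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  h00 * v0 + h10 * dt * m0 + h01 * v1 + h11 * dt * m1
}

# deterministic sub-seed derivation; keeps values in 32-bit integer range
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + k * 1000003) %% 2147483647)
}

# log-normal multiplicative jitter factors with mean 1 and coefficient of
# variation cv; sign-preserving by construction
.jitter_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
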
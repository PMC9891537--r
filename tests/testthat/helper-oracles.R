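# independent oracles and random-case generators shared across test files

# fixed-point iteration oracle for the mutual-inactivation steady state:
# alternate L = b_L/(beta1 + k_ci N), N = b_N/(beta2 + k_ci L) to convergence
mi_fixed_point_oracle <- function(p, ext = external_signal(),
                                  tol = 1e-12, max_iter = 1e5) {
  b1 <- p$beta + p$k_t * ext[[3]]
  b2 <- p$beta + p$k_t * ext[[1]]
  L <- p$b_L / b1; N <- p$b_N / b2
  for (i in seq_len(max_iter)) {
    L_new <- p$b_L / (b1 + p$k_ci * N)
    N_new <- p$b_N / (b2 + p$k_ci * L_new)
    if (abs(L_new - L) < tol * max(L_new, 1) &&
        abs(N_new - N) < tol * max(N_new, 1)) {
      L <- L_new; N <- N_new
      break
    }
    L <- L_new; N <- N_new
  }
  c(L = L, N = N, S = p$k_t * N * ext[[1]] / p$beta_S)
}

# log-uniform draw over a factor-of-ten band around the baseline values
draw_params <- function() {
  lu <- function(x) x * 10^stats::runif(1, -1, 1)
  notch_params(b_L = lu(200), b_N = lu(200), k_d = lu(1e-4), k_t = lu(5e-5),
               k_ci = lu(6e-4), beta = lu(0.1), beta_S = lu(0.5))
}

draw_ext <- function() {
  lu <- function(x) x * 10^stats::runif(1, -1, 1)
  external_signal(L_ext = lu(1500), N_ext = lu(1500))
}

rel_diff <- function(a, b, floor = 1e-8) {
  abs(a - b) / pmax(abs(a), abs(b), floor * max(abs(a), abs(b), 1))
}

config_path <- function(name) {
  system.file("extdata", "configs", name, package = "notchdimer",
              mustWork = TRUE)
}
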
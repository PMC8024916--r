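# shared fixture builders and independent oracles

toy_panel <- function() {
  # ten samples over three catalog haplotypes + one off-catalog string
  h2 <- "ERIGMKDRQ"  # allotype 2
  h8 <- "EPMGMRDRE"  # allotype 8
  h10 <- "EPIGVRNQE" # allotype 10
  hx <- "EPIGMKDRE"  # unassigned
  tibble::tibble(
    sample = sprintf("t%02d", 1:10),
    population = rep(c("EUR", "EAS"), each = 5),
    hap1 = c(h2, h2, h8, h8, h10, h2, h8, h2, hx, h10),
    hap2 = c(h2, h8, h8, h10, h10, h8, h2, h2, h2, h8)
  )
}

# closed-form simple linear regression (normal equations), the oracle for
# lm-backed fits
ols_line <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  a <- (sy - b * sx) / n
  c(intercept = a, slope = b)
}

# textbook tricube local-linear smoother (no robustness iterations);
# independent oracle for lowess_smooth
tricube_lowess <- function(x, y, span) {
  n <- length(x)
  q <- max(2L, min(n, floor(span * n + 1e-7)))
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d, partial = q)[q]
    w <- numeric(n)
    idx <- d <= h & d < Inf
    if (h > 0) {
      w[idx] <- (1 - pmin(d[idx] / h, 1)^3)^3
    } else {
      w[idx] <- 1
    }
    sw <- sum(w)
    w <- w / sw
    xb <- sum(w * x)
    vx <- sum(w * (x - xb)^2)
    if (sqrt(vx) > 1e-3 * diff(range(x))) {
      b <- sum(w * (x - xb) * y) / vx
      out[i] <- sum(w * y) + b * (x[i] - xb)
    } else {
      out[i] <- sum(w * y)
    }
  }
  list(x = x, y = out)
}

# independent MM progress-curve generator (deSolve, own right-hand side)
mm_progress <- function(kcat, KM, E, s0, times) {
  sol <- deSolve::ode(
    y = c(S = s0), times = times,
    func = function(t, y, p) list(-kcat * E * y[1] / (KM + y[1])),
    parms = NULL, rtol = 1e-10, atol = 1e-16)
  tibble::tibble(time = times, conc = s0 - sol[, "S"])
}

# averaged replicated noisy cascade series (study-style triplicate)
replicated_cascade <- function(spec_args, n_rep = 3, seed0 = 10) {
  reps <- lapply(seq_len(n_rep), function(k) {
    allokin::simulate_cascade(do.call(allokin::cascade_spec,
                                      c(spec_args,
                                        list(noise_cv = 0.05,
                                             seed = seed0 + k))))
  })
  out <- dplyr::bind_rows(reps) |>
    dplyr::summarise(conc = mean(conc), .by = c(time, species))
  attr(out, "E") <- attr(reps[[1]], "E")
  out
}
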
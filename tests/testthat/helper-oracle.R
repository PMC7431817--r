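# log-space residuals of the full 12-species system; the conformational,
# binding and dimerization relations are linear in log concentrations, the
# conservation law is a log-sum-exp. Solved numerically from a naive start,
# this is an oracle independent of the closed-form quadratic.
full_system_logresid <- function(u, p, Rtot, L) {
  c(u["CI"] - log(p[["K2"]]) - u["EI"],
    u["CI"] - log(p[["K1"]]) - u["CA"],
    u["EI"] - log(p[["K1"]]) - u["EA"],
    u["EI"] + log(L) - log(p[["K3"]]) - u["EIL"],
    u["EA"] + log(L) - log(p[["K3"]]) - u["EAL"],
    2 * u["EI"] - log(p[["K4"]]) - u["DES"],
    u["DES"] + log(L) - log(p[["K5"]]) - u["DESL"],
    u["DESL"] + log(L) - log(p[["K6"]]) - u["DES2L"],
    2 * u["EA"] - log(p[["K7"]]) - u["DEA"],
    u["DEA"] + log(L) - log(p[["K8"]]) - u["DEAL"],
    u["DEAL"] + log(L) - log(p[["K9"]]) - u["DEA2L"],
    log(sum(exp(u[1:6])) + 2 * sum(exp(u[7:12]))) - log(Rtot))
}

brute_force_state <- function(p, Rtot, L) {
  nm <- c("CI", "CA", "EI", "EA", "EIL", "EAL",
          "DES", "DESL", "DES2L", "DEA", "DEAL", "DEA2L")
  u0 <- stats::setNames(rep(log(Rtot / 18), 12), nm)
  r <- pracma::fsolve(function(u) {
    names(u) <- nm
    full_system_logresid(u, p, Rtot, L)
  }, x0 = u0, tol = 1e-13, maxiter = 300)
  stats::setNames(exp(r$x), nm)
}
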
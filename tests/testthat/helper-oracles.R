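# Independent oracles used across the suite.

# Closed-form one-compartment, first-order-absorption (Bateman) solution.
bateman_conc <- function(dose_nmol, ka, ke, v1, t) {
  dose_nmol * ka / (v1 * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

# Pure-R re-expression of the gut model rate laws, written from the model
# description (not translated from the C source), used to cross-check the
# compiled derivatives.
r_gut_rhs <- function(t, y, p) {
  ks <- p[sprintf("ks%d", 1:9)]; kf <- p[sprintf("kf%d", 1:9)]
  gopen <- p[sprintf("gopen%d", 1:9)]
  kabs <- p[sprintf("kabs%d", 1:8)]; kbaso <- p[sprintf("kbaso%d", 1:8)]
  kmet <- p[sprintf("kmet%d", 1:8)]
  pgpV <- p[sprintf("pgpV%d", 1:8)]; pgpKA <- p[sprintf("pgpKA%d", 1:8)]
  S <- y[1:9]; L <- y[10:18]; E <- y[19:26]
  Ac <- y[27]; Ap <- y[28]; tau <- y[34]
  byp <- p["bypass"] > 0.5

  stot <- sum(pmax(S, 0))
  w <- if (stot > 1e-10) sum(pmax(S, 0)[gopen > 0.5]) / stot else 0
  te <- tau - p["tlag"]
  h <- 0
  if (te > 0) {
    te <- max(te, 1e-9)
    Fv <- p["fmax"] * (1 - exp(-(te^p["beta"]) / p["alpha"]))
    dF <- p["fmax"] * exp(-(te^p["beta"]) / p["alpha"]) * p["beta"] *
      te^(p["beta"] - 1) / p["alpha"]
    h <- if (100 - Fv > 1e-9) dF / (100 - Fv) else p["hcap"]
    h <- max(min(h, p["hcap"]), 0)
  }
  rel <- ifelse(gopen > 0.5, h * S, 0)

  dS <- c(-ks[1] * S[1] - rel[1],
          ks[1:8] * S[1:8] - ks[2:9] * S[2:9] - rel[2:9])
  absf <- kabs * L[2:9]
  pgp <- ifelse(pgpV > 0, pgpV * pmax(E, 0) / (pgpKA + pmax(E, 0)), 0)
  portal <- if (byp) absf else kbaso * E
  met <- if (byp) rep(0, 8) else kmet * E
  dE <- if (byp) rep(0, 8) else absf - kbaso * E - met - pgp
  dL <- c(rel[1] - kf[1] * L[1],
          rel[2:9] + kf[1:8] * L[1:8] - kf[2:9] * L[2:9] - absf +
            (if (byp) 0 else pgp))
  dAc <- (1 - p["EH"]) * sum(portal) -
    (p["kH"] + p["kR"] + p["k12"]) * Ac + p["k21"] * Ap
  dAp <- p["k12"] * Ac - p["k21"] * Ap
  list(c(dS, dL, dE, dAc, dAp,
         sum(met),
         p["EH"] * sum(portal) + p["kH"] * Ac,
         p["kR"] * Ac,
         ks[9] * S[9],
         kf[9] * L[9],
         w,
         portal))
}

# Mixed-model crossover oracle: REML fit with sequence, period, treatment
# fixed and subject random; 90% CI rebuilt from the reported SE and df.
# `boundary` flags fits where the subject variance component collapsed to
# the zero boundary; there the constrained REML solution no longer equals
# the classical within-subject contrast (which is the interior solution).
lme_crossover_ci <- function(table) {
  d <- table
  d$subject <- factor(d$subject)
  d$sequence <- factor(d$sequence)
  d$period <- factor(d$period)
  d$treatment <- factor(d$treatment, levels = c("R", "T"))
  d$logv <- log(d$value)
  fit <- nlme::lme(logv ~ sequence + period + treatment, random = ~ 1 | subject,
                   data = d, method = "REML")
  tt <- summary(fit)$tTable["treatmentT", ]
  est <- tt[["Value"]]; se <- tt[["Std.Error"]]; df <- tt[["DF"]]
  vc <- nlme::VarCorr(fit)
  sd_subj <- as.numeric(vc["(Intercept)", "StdDev"])
  sd_resid <- as.numeric(vc["Residual", "StdDev"])
  c(gmr = exp(est), ci_low = exp(est + qt(0.05, df) * se),
    ci_high = exp(est + qt(0.95, df) * se),
    boundary = as.numeric(sd_subj < 1e-3 * sd_resid))
}

# Random balanced 2x2 crossover dataset on the log scale.
random_crossover_data <- function(n = 12, delta = 0, sigma_wsv = 0.15,
                                  sigma_bsv = 0.4) {
  seqs <- rep(c("TR", "RT"), length.out = n)
  bsv <- rnorm(n, 0, sigma_bsv)
  rows <- lapply(seq_len(n), function(i) {
    trts <- strsplit(seqs[i], "")[[1]]
    data.frame(subject = i, sequence = seqs[i], period = 1:2,
               treatment = trts,
               value = exp(2 + bsv[i] + delta * (trts == "T") +
                             0.05 * (1:2 == 2) + rnorm(2, 0, sigma_wsv)))
  })
  do.call(rbind, rows)
}
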
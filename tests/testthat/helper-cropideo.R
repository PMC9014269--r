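# Shared fixtures and independent oracles for the test suite.

# Independent brute-force light partition: plain R loops over cells and
# layers following the documented algorithm (crown-disc footprint, leaf
# profile slabs, Beer-Lambert per column, proportional element sharing,
# shading at the median leaf height excluding own leaves).
light_oracle <- function(plants, par, Lx, Ly, cellSize, layerSize, k) {
  ncx <- max(1, round(Lx / cellSize)); ncy <- max(1, round(Ly / cellSize))
  cw <- Lx / ncx; ch <- Ly / ncy; cellArea <- cw * ch
  n <- nrow(plants)
  maxH <- max(plants$height)
  nl <- max(1, ceiling(maxH / layerSize))
  ncell <- ncx * ncy
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    r <- plants$width[i] / 200
    got <- integer(0)
    for (cx in floor((plants$x[i] - r) / cw):floor((plants$x[i] + r) / cw))
      for (cy in floor((plants$y[i] - r) / ch):
                 floor((plants$y[i] + r) / ch)) {
        dx <- (cx + 0.5) * cw - plants$x[i]
        dy <- (cy + 0.5) * ch - plants$y[i]
        if (dx^2 + dy^2 <= r^2 + 1e-12) {
          wx <- ((cx %% ncx) + ncx) %% ncx
          wy <- ((cy %% ncy) + ncy) %% ncy
          got <- c(got, wy * ncx + wx + 1)
        }
      }
    if (!length(got)) {
      wx <- ((floor(plants$x[i] / cw) %% ncx) + ncx) %% ncx
      wy <- ((floor(plants$y[i] / ch) %% ncy) + ncy) %% ncy
      got <- wy * ncx + wx + 1
    }
    cells[[i]] <- sort(unique(got))
  }
  lad <- matrix(0, nl, ncell)
  frac <- matrix(0, n, nl)
  for (i in seq_len(n)) {
    if (plants$leafArea[i] <= 0 || plants$height[i] <= 0) next
    laiPerCell <- plants$leafArea[i] / length(cells[[i]]) * 1e-4 / cellArea
    Fprev <- 0
    topl <- min(nl, ceiling(plants$height[i] / layerSize))
    for (l in seq_len(topl)) {
      ztop <- min(l * layerSize, plants$height[i])
      Fcur <- leaf_profile_cdf(ztop / plants$height[i], plants$rlh[i],
                               plants$brlh[i])
      frac[i, l] <- laiPerCell * (Fcur - Fprev)
      Fprev <- Fcur
      for (cc in cells[[i]]) lad[l, cc] <- lad[l, cc] + frac[i, l]
    }
  }
  Itop <- matrix(par, nl + 1, ncell)
  for (l in nl:1)
    Itop[l, ] <- Itop[l + 1, ] * exp(-k * lad[l, ])
  absorbed <- numeric(n)
  for (i in seq_len(n)) {
    for (l in seq_len(nl)) {
      if (frac[i, l] <= 0) next
      for (cc in cells[[i]]) {
        L <- lad[l, cc]
        if (L <= 0) next
        absorbed[i] <- absorbed[i] +
          Itop[l + 1, cc] * (1 - exp(-k * L)) * frac[i, l] / L * cellArea
      }
    }
  }
  cumAbove <- matrix(0, nl + 1, ncell)
  for (l in nl:1) cumAbove[l, ] <- cumAbove[l + 1, ] + lad[l, ]
  shading <- numeric(n)
  for (i in seq_len(n)) {
    if (plants$height[i] <= 0) next
    zm <- plants$height[i] * plants$rlh[i]
    lz <- min(nl - 1, max(0, floor(zm / layerSize)))
    own <- 0
    if (plants$leafArea[i] > 0) {
      Fz <- leaf_profile_cdf((lz + 1) * layerSize /
                               max(plants$height[i], 1e-9),
                             plants$rlh[i], plants$brlh[i])
      own <- (1 - Fz) * plants$leafArea[i] / length(cells[[i]]) * 1e-4 /
        cellArea
    }
    tr <- vapply(cells[[i]], function(cc)
      exp(-k * max(cumAbove[lz + 2, cc] - own, 0)), numeric(1))
    shading[i] <- min(max(1 - mean(tr), 0), 1 - 1e-9)
  }
  list(absorbedMJ = absorbed, shading = shading)
}

# A synthetic variety with simple round numbers, convenient for closed-form
# checks (HM = 20, b_HM = 0.3 etc. at every stage).
toy_variety <- function(mu_HM = 0.4, name = "toy") {
  base <- pea_reference_varieties()$Kayanne
  v <- base
  v$name <- name
  cst <- function(x) rep(x, 11)
  v$stages$SLA <- cst(150); v$stages$LBR <- cst(0.8)
  v$stages$HM <- cst(20); v$stages$b_HM <- cst(0.3)
  v$stages$WM <- cst(10); v$stages$b_WM <- cst(0.4)
  v$stages$RLH <- cst(0.5); v$stages$b_RLH <- cst(2)
  v$stages$mu_SLA <- cst(0.08); v$stages$mu_LBR <- cst(0.05)
  v$stages$mu_HM <- cst(mu_HM); v$stages$mu_WM <- cst(-0.1)
  v$stages$mu_RLH <- cst(0.02)
  validate_variety(v)
  v
}

# Small shared simulation inputs (built once per test file load).
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      vs <- pea_reference_varieties()
      pool <- gen_weed_pool("complete", seed = 1)
      cache <<- list(
        varieties = vs,
        situations = situation_presets(),
        pool = pool,
        bank = new_seed_bank(pool),
        weather = gen_weather(6, seed = 7))
    }
    cache
  }
})
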
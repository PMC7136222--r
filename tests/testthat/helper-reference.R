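# Intentionally naive scalar reference for the harmonization decision tree:
# per-cell loops, longhand formulas, no reuse of the package's vectorized
# paths. Used as the ground-truth oracle for the end-to-end comparison.

ref_clamp <- function(x, lo, hi) min(max(x, lo), hi)

# value + SE of the standard fractional-allocation path for one cell
ref_standard_cell <- function(mw, sw, mg, sg, mc, sc, hclass, ua_crop,
                              ua_grass, tc_pct, tc_sd) {
  q <- min(tc_pct / 80, 1)
  sq <- tc_sd / 80
  if (hclass == "crop") {
    p <- ua_crop; mi <- mc; si <- sc; mj <- mg; sj <- sg
  } else {
    p <- ua_grass; mi <- mg; si <- sg; mj <- mc; sj <- sc
  }
  d <- sqrt(p * (1 - p))
  dop <- if (p > 0) d / p else 0
  mh <- mi * p + mj * (1 - p)
  sh <- sqrt((p * si)^2 + (mi * d)^2 + ((1 - p) * sj)^2 +
               (mj * (1 - p) * dop)^2)
  mt <- mw + mh * (1 - q)
  st <- sqrt(sw^2 + (q * sh)^2 + (mh * sq)^2)
  c(mt, st)
}

# scalar reference of run_harmonization for one pool.
# decision quantities (tundra vs woody AGBC, tree cover) always come from
# the AGBC stack, matching the single-decision-per-cell contract.
ref_harmonize <- function(stack, pool = "agbc") {
  inp <- stack$inputs
  g <- inp$woody$mean$grid
  lats <- row_latitudes(g)
  ua_crop <- inp$herb_ua[["crop"]]
  ua_grass <- inp$herb_ua[["grass"]]

  pl <- if (pool == "agbc") inp[c("woody", "grass", "crop", "tundra")]
        else stack$bgb_layers[c("woody", "grass", "crop", "tundra")]

  out_m <- matrix(NA_real_, g$n_rows, g$n_cols)
  out_s <- matrix(NA_real_, g$n_rows, g$n_cols)
  for (i in seq_len(g$n_rows)) {
    for (j in seq_len(g$n_cols)) {
      lc <- inp$landcover$values[i, j]
      if (!is.na(lc) && lc == 210) next  # water is masked at the end
      mw <- pl$woody$mean$values[i, j]; sw <- pl$woody$se$values[i, j]
      mg <- pl$grass$mean$values[i, j]; sg <- pl$grass$se$values[i, j]
      mc <- pl$crop$mean$values[i, j]; sc <- pl$crop$se$values[i, j]
      mt <- pl$tundra$mean$values[i, j]; st <- pl$tundra$se$values[i, j]
      tc_pct <- inp$treecover$mean$values[i, j]
      tc_sd <- inp$treecover$se$values[i, j]
      hclass <- inp$herbaceous_class$values[i, j]
      biome <- inp$biome$values[i, j]
      sparse <- !is.na(inp$sparse_mask$values[i, j]) &&
        inp$sparse_mask$values[i, j] > 0
      agbc_t <- inp$tundra$mean$values[i, j]
      agbc_w <- inp$woody$mean$values[i, j]
      if (anyNA(c(mw, sw, mg, sg, mc, sc, mt, st, tc_pct, tc_sd)) ||
          is.na(hclass) || is.na(biome)) next

      std <- ref_standard_cell(mw, sw, mg, sg, mc, sc, hclass,
                               ua_crop, ua_grass, tc_pct, tc_sd)
      wg <- ref_standard_cell(mw, sw, mg, sg, mc, sc, "grass",
                              ua_crop, ua_grass, tc_pct, tc_sd)
      in_biome <- biome %in% c("tundra", "boreal")

      south <- if (in_biome && sparse) c(mt, st) else std
      north <- if (!in_biome) {
        std
      } else if (sparse) {
        c(mt, st)
      } else if (tc_pct < 10 ||
                 (!is.na(agbc_t) && (is.na(agbc_w) || agbc_t > agbc_w))) {
        c(mt, st)
      } else {
        wg
      }

      w <- ref_clamp((lats[i] - 59) / 2, 0, 1)
      if (w == 1) {
        out_m[i, j] <- north[1]; out_s[i, j] <- north[2]
      } else if (w == 0) {
        out_m[i, j] <- south[1]; out_s[i, j] <- south[2]
      } else {
        out_m[i, j] <- w * north[1] + (1 - w) * south[1]
        out_s[i, j] <- sqrt((w * north[2])^2 + ((1 - w) * south[2])^2)
      }
    }
  }
  list(mean = out_m, se = out_s)
}
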
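# Multiple-QTL models: penalized-LOD stepwise search, per-term variance
# attribution, and fine-grid position refinement. Model fits use plain
# Haley-Knott regression on the expected genotype scores with sex as an
# additive covariate; each locus contributes an additive and a dominance
# column, each locus-pair interaction the four products of those columns.
# The penalized LOD is
#   pLOD = LOD - T_main * #loci - T_heavy * #heavy - T_light * #light,
# where within each connected component of the interaction graph one
# interaction is heavy and the remainder are light.

# column index in the flattened score matrices nearest to (chr, pos)
locus_col <- function(pos_tbl, chr, pos) {
  rows <- which(pos_tbl$chr == as.character(chr))
  if (!length(rows)) abort(sprintf("chromosome %s not on the grid", chr))
  rows[which.min(abs(pos_tbl$pos_cM[rows] - pos))]
}

# count heavy/light interactions from the interaction graph
interaction_penalty_counts <- function(n_loci, interactions) {
  if (is.null(interactions) || nrow(interactions) == 0) {
    return(c(heavy = 0L, light = 0L))
  }
  g <- igraph::make_empty_graph(n = n_loci, directed = FALSE)
  g <- igraph::add_edges(g, rbind(interactions$q1, interactions$q2))
  memb <- igraph::components(g)$membership
  edges_per_comp <- tapply(
    rep(1L, nrow(interactions)),
    memb[interactions$q1], sum
  )
  heavy <- length(edges_per_comp)
  light <- nrow(interactions) - heavy
  c(heavy = heavy, light = light)
}

model_design <- function(sc, y_len, sex, cols, interactions) {
  Xnull <- if (is.null(sex)) matrix(1, y_len, 1) else cbind(1, sex)
  p0 <- ncol(Xnull)
  nl <- length(cols)
  ni <- if (is.null(interactions)) 0L else nrow(interactions)
  X <- matrix(0, y_len, p0 + 2 * nl + 4 * ni)
  X[, seq_len(p0)] <- Xnull
  for (k in seq_along(cols)) {
    X[, p0 + 2 * k - 1] <- sc$X[, cols[k]]
    X[, p0 + 2 * k] <- sc$Z[, cols[k]]
  }
  if (ni > 0) {
    for (r in seq_len(ni)) {
      i <- cols[interactions$q1[r]]
      j <- cols[interactions$q2[r]]
      base <- p0 + 2 * nl + 4 * (r - 1)
      X[, base + 1] <- sc$X[, i] * sc$X[, j]
      X[, base + 2] <- sc$X[, i] * sc$Z[, j]
      X[, base + 3] <- sc$Z[, i] * sc$X[, j]
      X[, base + 4] <- sc$Z[, i] * sc$Z[, j]
    }
  }
  list(X = X, Xnull = Xnull)
}

# RSS after adding columns A to a design whose residualised response is yr:
# project A off Xcur first, then take the explained quadratic form.
added_rss <- function(Xcur, rss_cur, y, A) {
  Ar <- resid_against(Xcur, A)
  yr <- as.vector(resid_against(Xcur, matrix(y)))
  S <- crossprod(Ar)
  sy <- as.vector(crossprod(Ar, yr))
  max(quad_rss(S, sy, rss_cur), 1e-12)
}

model_plod <- function(lod, n_loci, interactions, penalties) {
  cnt <- interaction_penalty_counts(n_loci, interactions)
  lod - penalties$T_main * n_loci - penalties$T_heavy * cnt[["heavy"]] -
    penalties$T_light * cnt[["light"]]
}

#' Fit a multiple-QTL model at fixed positions
#'
#' @param probs A `geno_probs`.
#' @param phenotype Numeric phenotype vector.
#' @param sex Optional additive sex covariate.
#' @param loci Tibble (`chr`, `pos_cM`) of QTL positions.
#' @param interactions Optional tibble (`q1`, `q2`) of interacting locus pairs
#'   (row indices into `loci`).
#' @param penalties A `penalty_set` (needed for the penalized LOD; may be
#'   `NULL`, in which case `plod` is `NA`).
#' @return An object of class `qtl_model`.
#' @export
fit_qtl_model <- function(probs, phenotype, sex = NULL, loci,
                          interactions = NULL, penalties = NULL) {
  sc <- probs_scores(probs)
  fit_qtl_model_sc(sc, phenotype, sex, loci, interactions, penalties)
}

fit_qtl_model_sc <- function(sc, y, sex, loci, interactions = NULL,
                             penalties = NULL) {
  n <- length(y)
  loci <- as_tibble(loci)
  if (nrow(loci) > 0) loci$chr <- as.character(loci$chr)
  cols <- if (nrow(loci)) {
    vapply(seq_len(nrow(loci)),
           function(r) locus_col(sc$pos, loci$chr[r], loci$pos_cM[r]),
           integer(1))
  } else integer(0)
  des <- model_design(sc, n, sex, cols, interactions)
  rss0 <- ols_rss(des$Xnull, y)
  rss1 <- if (nrow(loci)) max(ols_rss(des$X, y), 1e-12) else rss0
  lod <- max(n / 2 * log10(rss0 / rss1), 0)
  plod <- if (!is.null(penalties)) {
    model_plod(lod, nrow(loci), interactions, penalties)
  } else NA_real_

  eff <- tibble(a = rep(NA_real_, nrow(loci)), d = rep(NA_real_, nrow(loci)))
  int_coef <- NULL
  if (nrow(loci)) {
    fit <- lm.fit(des$X, y)
    cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    p0 <- ncol(des$Xnull)
    for (r in seq_len(nrow(loci))) {
      eff$a[r] <- cf[p0 + 2 * r - 1]
      eff$d[r] <- cf[p0 + 2 * r]
    }
    if (!is.null(interactions) && nrow(interactions) > 0) {
      base <- p0 + 2 * nrow(loci)
      int_coef <- interactions
      int_coef$coef_xx <- cf[base + 4 * (seq_len(nrow(interactions)) - 1) + 1]
    }
  }

  structure(
    list(
      loci = dplyr::bind_cols(loci, eff),
      interactions = if (is.null(interactions)) {
        tibble(q1 = integer(), q2 = integer())
      } else as_tibble(interactions),
      lod = lod, plod = plod, rss = rss1, rss0 = rss0, n = n,
      penalties = penalties, cols = cols,
      locus_X = if (length(cols)) sc$X[, cols, drop = FALSE] else NULL,
      locus_Z = if (length(cols)) sc$Z[, cols, drop = FALSE] else NULL,
      terms = NULL, refinement = NULL
    ),
    class = "qtl_model"
  )
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf(
    "<qtl_model> %d loci, %d interactions | LOD %.2f | pLOD %s\n",
    nrow(x$loci), nrow(x$interactions), x$lod,
    if (is.na(x$plod)) "NA" else sprintf("%.2f", x$plod)
  ))
  if (nrow(x$loci)) print(as.data.frame(x$loci), row.names = FALSE)
  invisible(x)
}

#' Penalized forward/backward multiple-QTL model search
#'
#' Starting from the empty model, repeatedly augments the model with whichever
#' candidate maximises the penalized LOD: the best additional locus (from a
#' genome scan conditional on the current model) or the best new interaction
#' between current loci, up to `max_qtl` loci. The forward path is then pruned
#' backward to the empty model by repeatedly deleting the term whose removal
#' maximises the penalized LOD. The model with the highest penalized LOD
#' visited on either path is returned; when no visited model exceeds pLOD = 0
#' the empty model is returned (no QTL are declared).
#'
#' @param probs A `geno_probs`.
#' @param phenotype Numeric phenotype vector.
#' @param sex Optional additive sex covariate.
#' @param penalties A `penalty_set` from [derive_penalties()].
#' @param max_qtl Maximum number of loci considered (default 10).
#' @return A `qtl_model` (possibly empty), with per-term statistics filled in
#'   by [variance_explained()] when nonempty.
#' @export
stepwise_model_search <- function(probs, phenotype, sex = NULL, penalties,
                                  max_qtl = 10) {
  stopifnot(inherits(penalties, "penalty_set"))
  sc <- probs_scores(probs)
  y <- phenotype
  n <- length(y)
  Xnull <- if (is.null(sex)) matrix(1, n, 1) else cbind(1, sex)
  rss0 <- ols_rss(Xnull, y)

  empty_ints <- tibble(q1 = integer(), q2 = integer())
  state <- list(cols = integer(0), interactions = empty_ints)
  plod_of <- function(rss, st) {
    lod <- max(n / 2 * log10(rss0 / rss), 0)
    list(lod = lod,
         plod = model_plod(lod, length(st$cols), st$interactions, penalties))
  }
  state_rss <- function(st) {
    if (!length(st$cols)) return(rss0)
    des <- model_design(sc, n, sex, st$cols, st$interactions)
    max(ols_rss(des$X, y), 1e-12)
  }
  inter_cols <- function(c1, c2) {
    cbind(sc$X[, c1] * sc$X[, c2], sc$X[, c1] * sc$Z[, c2],
          sc$Z[, c1] * sc$X[, c2], sc$Z[, c1] * sc$Z[, c2])
  }
  visited <- list(list(state = state, plod = 0, lod = 0))
  cur_rss <- rss0
  cur_X <- Xnull

  # ---- forward: add the best locus or interaction at each step, up to
  # max_qtl loci; once at the cap, keep adding interactions only while they
  # improve the penalized LOD ----
  repeat {
    best_cand <- NULL
    best_plod <- -Inf
    at_cap <- length(state$cols) >= max_qtl
    if (!at_cap) {
      lods <- hk_scan_lods(y, cur_X, sc$X, sc$Z, NULL)
      lods[state$cols] <- -Inf
      j <- which.max(lods)
      rss_new <- cur_rss / 10^(2 * lods[j] / n)
      st <- state
      st$cols <- c(st$cols, j)
      f <- plod_of(rss_new, st)
      best_cand <- list(state = st, rss = rss_new, fit = f)
      best_plod <- f$plod
    }
    if (length(state$cols) >= 2) {
      pairs <- utils::combn(length(state$cols), 2)
      have <- paste(state$interactions$q1, state$interactions$q2)
      for (kk in seq_len(ncol(pairs))) {
        if (paste(pairs[1, kk], pairs[2, kk]) %in% have) next
        A <- inter_cols(state$cols[pairs[1, kk]], state$cols[pairs[2, kk]])
        rss_new <- added_rss(cur_X, cur_rss, y, A)
        st <- state
        st$interactions <- dplyr::bind_rows(
          st$interactions, tibble(q1 = pairs[1, kk], q2 = pairs[2, kk])
        )
        f <- plod_of(rss_new, st)
        if (f$plod > best_plod) {
          best_cand <- list(state = st, rss = rss_new, fit = f)
          best_plod <- f$plod
        }
      }
    }
    if (is.null(best_cand)) break
    cur_plod <- visited[[length(visited)]]$plod
    if (at_cap && best_plod <= cur_plod) break
    state <- best_cand$state
    cur_rss <- best_cand$rss
    cur_X <- model_design(sc, n, sex, state$cols, state$interactions)$X
    visited <- c(visited, list(list(state = state, plod = best_cand$fit$plod,
                                    lod = best_cand$fit$lod)))
  }

  # ---- backward: delete the term whose removal maximises pLOD, down to the
  # empty model (a deleted locus takes its interactions with it) ----
  while (length(state$cols) > 0) {
    cand <- list()
    if (nrow(state$interactions) > 0) {
      for (r in seq_len(nrow(state$interactions))) {
        st <- state
        st$interactions <- st$interactions[-r, ]
        cand <- c(cand, list(st))
      }
    }
    for (l in seq_along(state$cols)) {
      st <- state
      st$cols <- st$cols[-l]
      keep <- !(st$interactions$q1 == l | st$interactions$q2 == l)
      ints <- st$interactions[keep, ]
      ints$q1 <- ints$q1 - (ints$q1 > l)
      ints$q2 <- ints$q2 - (ints$q2 > l)
      st$interactions <- ints
      cand <- c(cand, list(st))
    }
    fits <- lapply(cand, function(st) plod_of(state_rss(st), st))
    best <- which.max(vapply(fits, `[[`, numeric(1), "plod"))
    state <- cand[[best]]
    visited <- c(visited, list(list(state = state, plod = fits[[best]]$plod,
                                    lod = fits[[best]]$lod)))
  }

  plods <- vapply(visited, `[[`, numeric(1), "plod")
  bi <- which.max(plods)
  if (plods[bi] <= 0 || length(visited[[bi]]$state$cols) == 0) {
    mdl <- fit_qtl_model_sc(sc, y, sex, tibble(chr = character(),
                                               pos_cM = numeric()),
                            NULL, penalties)
    return(mdl)
  }
  st <- visited[[bi]]$state
  loci <- sc$pos[st$cols, c("chr", "pos_cM")]
  mdl <- fit_qtl_model_sc(sc, y, sex, loci, st$interactions, penalties)
  mdl$terms <- variance_explained_sc(mdl, sc, y, sex)
  mdl
}

#' Per-term variance attribution
#'
#' Refits the model without each term in turn: a locus term is dropped together
#' with its interactions, an interaction term alone. The percent variance
#' explained by a term is `100 * (RSS_reduced - RSS_full) / TSS` (TSS about the
#' phenotype mean) and the dropped LOD is `LOD_full - LOD_reduced`.
#'
#' @param model A nonempty `qtl_model`.
#' @param probs The `geno_probs` the model was fitted on.
#' @param phenotype,sex As used for the fit.
#' @return A tibble: `term`, `chr`, `pos_cM`, `pct_var`, `lod_drop`.
#' @export
variance_explained <- function(model, probs, phenotype, sex = NULL) {
  variance_explained_sc(model, probs_scores(probs), phenotype, sex)
}

variance_explained_sc <- function(model, sc, y, sex = NULL) {
  if (nrow(model$loci) == 0) abort("model is empty; nothing to attribute")
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  full_rss <- model$rss
  ints <- model$interactions
  rows <- list()
  for (l in seq_len(nrow(model$loci))) {
    keep <- setdiff(seq_len(nrow(model$loci)), l)
    ki <- ints[!(ints$q1 == l | ints$q2 == l), ]
    ki$q1 <- ki$q1 - (ki$q1 > l)
    ki$q2 <- ki$q2 - (ki$q2 > l)
    des <- model_design(sc, n, sex, model$cols[keep], ki)
    rss_red <- if (length(keep)) max(ols_rss(des$X, y), 1e-12) else model$rss0
    rows[[length(rows) + 1]] <- tibble(
      term = sprintf("%s@%.1f", model$loci$chr[l], model$loci$pos_cM[l]),
      chr = model$loci$chr[l], pos_cM = model$loci$pos_cM[l],
      pct_var = 100 * (rss_red - full_rss) / tss,
      lod_drop = n / 2 * log10(rss_red / full_rss)
    )
  }
  if (nrow(ints) > 0) {
    for (r in seq_len(nrow(ints))) {
      des <- model_design(sc, n, sex, model$cols, ints[-r, ])
      rss_red <- max(ols_rss(des$X, y), 1e-12)
      rows[[length(rows) + 1]] <- tibble(
        term = sprintf(
          "%s@%.1f:%s@%.1f",
          model$loci$chr[ints$q1[r]], model$loci$pos_cM[ints$q1[r]],
          model$loci$chr[ints$q2[r]], model$loci$pos_cM[ints$q2[r]]
        ),
        chr = NA_character_, pos_cM = NA_real_,
        pct_var = 100 * (rss_red - full_rss) / tss,
        lod_drop = n / 2 * log10(rss_red / full_rss)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Refine QTL positions on a fine grid
#'
#' Recomputes genotype probabilities at a fine step (default 0.1 cM) within a
#' window around each locus, and re-optimises each locus position in turn while
#' holding the others fixed (one pass over the loci). The model LOD never
#' decreases, since the incumbent position is always among the candidates. The
#' per-locus LOD curves from the refinement are stored in `$refinement` for
#' plotting and support-interval construction.
#'
#' @param model A nonempty `qtl_model`.
#' @param cross The `cross_data` the model derives from.
#' @param phenotype,sex As used for the fit.
#' @param step_cM Fine grid step (default 0.1).
#' @param window_cM Half-width of the refinement window (default 10).
#' @return The refined `qtl_model`.
#' @export
refine_positions <- function(model, cross, phenotype, sex = NULL,
                             step_cM = 0.1, window_cM = 10) {
  if (nrow(model$loci) == 0) abort("model is empty; nothing to refine")
  y <- phenotype
  n <- length(y)
  loci <- model$loci
  curves <- list()

  for (l in seq_len(nrow(loci))) {
    ch <- loci$chr[l]
    sub <- cross
    sub$map <- cross$map[cross$map$chr == ch, ]
    sub$geno <- cross$geno[, cross$map$chr == ch, drop = FALSE]
    probs_f <- genotype_probabilities(sub, step_cM = step_cM)
    sc_f <- probs_scores(probs_f)
    lo <- loci$pos_cM[l] - window_cM
    hi <- loci$pos_cM[l] + window_cM
    cand <- which(sc_f$pos$pos_cM >= lo & sc_f$pos$pos_cM <= hi)

    # fixed part of the design: all other loci (and their interactions via
    # full refits per candidate)
    lods <- vapply(cand, function(j) {
      trial <- loci
      trial$pos_cM[l] <- sc_f$pos$pos_cM[j]
      xl <- sc_f$X[, j]; zl <- sc_f$Z[, j]
      # assemble design: other loci from the coarse scores, this locus fine
      Xn <- if (is.null(sex)) matrix(1, n, 1) else cbind(1, sex)
      X <- Xn
      colsX <- list(); colsZ <- list()
      for (r in seq_len(nrow(loci))) {
        if (r == l) {
          colsX[[r]] <- xl; colsZ[[r]] <- zl
        } else {
          colsX[[r]] <- model$locus_X[, r]
          colsZ[[r]] <- model$locus_Z[, r]
        }
        X <- cbind(X, colsX[[r]], colsZ[[r]])
      }
      ints <- model$interactions
      if (nrow(ints) > 0) {
        for (r in seq_len(nrow(ints))) {
          X <- cbind(
            X,
            colsX[[ints$q1[r]]] * colsX[[ints$q2[r]]],
            colsX[[ints$q1[r]]] * colsZ[[ints$q2[r]]],
            colsZ[[ints$q1[r]]] * colsX[[ints$q2[r]]],
            colsZ[[ints$q1[r]]] * colsZ[[ints$q2[r]]]
          )
        }
      }
      rss1 <- max(ols_rss(X, y), 1e-12)
      max(n / 2 * log10(model$rss0 / rss1), 0)
    }, numeric(1))

    best <- which.max(lods)
    loci$pos_cM[l] <- sc_f$pos$pos_cM[cand[best]]
    curves[[l]] <- tibble(
      locus = l, chr = ch, pos_cM = sc_f$pos$pos_cM[cand], lod = lods
    )
    # update cached columns for this locus so later loci see the move
    model$locus_X[, l] <- sc_f$X[, cand[best]]
    model$locus_Z[, l] <- sc_f$Z[, cand[best]]
  }

  model$loci$pos_cM <- loci$pos_cM
  model$lod <- max(curves[[length(curves)]]$lod)
  if (!is.null(model$penalties)) {
    model$plod <- model_plod(model$lod, nrow(model$loci), model$interactions,
                             model$penalties)
  }
  model$refinement <- dplyr::bind_rows(curves)
  model
}
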
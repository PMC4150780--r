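# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's DP code paths: structures and hybrids are enumerated
# explicitly and scored by direct loop decomposition.

PAIRS_OK <- list(c("A","U"), c("U","A"), c("C","G"), c("G","C"),
                 c("G","U"), c("U","G"))

.pair_ok <- function(a, b) {
  any(vapply(PAIRS_OK, function(p) p[1] == a && p[2] == b, logical(1)))
}

.pair_code <- function(a, b) paste0(a, b)

.loopE_tab <- function(tab, size, extrap) {
  n <- length(tab)
  if (size <= n) return(tab[size])
  tab[n] + extrap * log(size / n)
}

oracle_model_terms <- function(model) {
  list(stack = model@stack, hairpin = model@hairpin, bulge = model@bulge,
       internal = model@internal, extrap = model@loop_extrap,
       term_au = model@terminal_au, init = model@duplex_init,
       a = model@ml_init, b = model@ml_branch, c = model@ml_unpaired,
       RT = model@RT, min_h = model@min_hairpin,
       max_side = model@max_loop_side)
}

# ---- duplex enumeration ----------------------------------------------------

# all antiparallel monotone hybrids between mi and tg, scored directly;
# returns min energy (NA if no favorable hybrid) and the full energy list
oracle_duplex_enum <- function(mi, tg, model) {
  mt <- oracle_model_terms(model)
  mch <- strsplit(mi, "")[[1]]; tch <- strsplit(tg, "")[[1]]
  M <- length(mch); T2 <- length(tch)
  energies <- numeric(0)
  gap_cost <- function(i1, j1, i2, j2) {
    a <- i2 - i1 - 1; b <- j1 - j2 - 1
    if (a > mt$max_side || b > mt$max_side) return(Inf)
    if (a == 0 && b == 0)
      return(mt$stack[.pair_code(mch[i1], tch[j1]),
                      .pair_code(mch[i2], tch[j2])])
    if (a == 0 || b == 0) return(.loopE_tab(mt$bulge, a + b, mt$extrap))
    .loopE_tab(mt$internal, a + b, mt$extrap)
  }
  weakp <- function(i, j) !(.pair_code(mch[i], tch[j]) %in% c("CG", "GC"))
  extend <- function(i, j, e) {
    # e includes init + first-pair terminal; close here:
    energies <<- c(energies, e + if (weakp(i, j)) mt$term_au else 0)
    if (i < M && j > 1) {
      for (i2 in (i + 1):M) for (j2 in 1:(j - 1)) {
        if (!.pair_ok(mch[i2], tch[j2])) next
        g <- gap_cost(i, j, i2, j2)
        if (is.finite(g)) extend(i2, j2, e + g)
      }
    }
  }
  for (i in 1:M) for (j in 1:T2) {
    if (.pair_ok(mch[i], tch[j]))
      extend(i, j, mt$init + if (weakp(i, j)) mt$term_au else 0)
  }
  best <- if (length(energies)) min(energies) else NA_real_
  if (!is.na(best) && best > 0) best <- NA_real_
  list(dG = best, all = energies)
}

# ---- secondary-structure enumeration ---------------------------------------

# all pseudoknot-free structures of [1..n] (allowed pairs, hairpin >= min_h)
# as lists of 2-col pair matrices (includes the empty structure)
oracle_enum_structures <- function(seq, model) {
  mt <- oracle_model_terms(model)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (j - i + 1 <= mt$min_h) return(list(matrix(integer(), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j) # i unpaired
    for (k in (i + mt$min_h + 1):j) {
      if (k > j) break
      if (!.pair_ok(ch[i], ch[k])) next
      inner <- rec(i + 1, k - 1)
      outer <- if (k + 1 <= j) rec(k + 1, j) else list(matrix(integer(), 0, 2))
      for (A in inner) for (B in outer)
        out <- c(out, list(rbind(matrix(c(i, k), 1, 2), A, B)))
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# direct loop-decomposition energy of one structure; Inf = outside the model
oracle_structure_energy <- function(seq, pairs, model) {
  mt <- oracle_model_terms(model)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  partner <- integer(n)
  if (nrow(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  children_of <- function(i, j) {
    kids <- NULL; k <- i + 1
    while (k <= j - 1) {
      if (partner[k] > k) { kids <- rbind(kids, c(k, partner[k])); k <- partner[k] + 1 }
      else k <- k + 1
    }
    kids
  }
  E <- 0
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    i <- min(pairs[r, ]); j <- max(pairs[r, ])
    kids <- children_of(i, j)
    if (is.null(kids)) {
      E <- E + .loopE_tab(mt$hairpin, j - i - 1, mt$extrap)
    } else if (nrow(kids) == 1) {
      k <- kids[1, 1]; l <- kids[1, 2]
      l1 <- k - i - 1; l2 <- j - l - 1
      if (l1 > mt$max_side || l2 > mt$max_side) return(Inf)
      if (l1 == 0 && l2 == 0)
        E <- E + mt$stack[.pair_code(ch[i], ch[j]), .pair_code(ch[k], ch[l])]
      else if (l1 == 0 || l2 == 0)
        E <- E + .loopE_tab(mt$bulge, l1 + l2, mt$extrap)
      else
        E <- E + .loopE_tab(mt$internal, l1 + l2, mt$extrap)
    } else {
      unp <- (j - i - 1) - sum(kids[, 2] - kids[, 1] + 1)
      E <- E + mt$a + mt$b * (nrow(kids) + 1) + mt$c * unp
    }
  }
  E
}

# Boltzmann-averaged ensemble quantities by full enumeration
oracle_ensemble <- function(seq, model, mask_interval = NULL) {
  structures <- oracle_enum_structures(seq, model)
  n <- nchar(seq)
  keep_w <- numeric(0); unp <- matrix(0, 0, n)
  kept <- list()
  for (s in structures) {
    if (!is.null(mask_interval) && nrow(s)) {
      lo <- mask_interval[1] + 1; hi <- mask_interval[2]
      if (hi >= lo && any(s >= lo & s <= hi)) next
    }
    E <- oracle_structure_energy(seq, s, model)
    if (!is.finite(E)) next
    w <- exp(-E / model@RT)
    keep_w <- c(keep_w, w)
    u <- rep(1, n)
    if (nrow(s)) u[c(s[, 1], s[, 2])] <- 0
    unp <- rbind(unp, u)
    kept[[length(kept) + 1L]] <- s
  }
  Z <- sum(keep_w)
  list(Z = Z, logZ = log(Z),
       p_unpaired = colSums(unp * keep_w) / Z,
       weights = keep_w, structures = kept)
}

# dot-bracket for an enumerated structure (to match sampler output)
oracle_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- min(pairs[r, ]); j <- max(pairs[r, ])
      db[i] <- "("; db[j] <- ")"
    }
  }
  paste(db, collapse = "")
}

# ---- misc oracles ----------------------------------------------------------

random_rna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Fisher two-sided p by fixed-margin hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n2, k)
  pobs <- dhyper(a, m, n2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# seed classification oracle: direct string comparison per definition
oracle_classify_seed <- function(mirna, target, t1pos) {
  mch <- strsplit(mirna, "")[[1]]
  tch <- strsplit(target, "")[[1]]
  wc <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "C" && b == "G") || (a == "G" && b == "C")
  }
  match_range <- function(k1, k2) {
    for (k in k1:k2) {
      tp <- t1pos - (k - 1)
      if (tp < 1 || tp > length(tch)) return(FALSE)
      if (!wc(mch[k], tch[tp])) return(FALSE)
    }
    TRUE
  }
  hasA1 <- t1pos >= 1 && t1pos <= length(tch) && tch[t1pos] == "A"
  if (match_range(2, 8) && hasA1) return("8mer")
  if (match_range(2, 8)) return("7mer-m8")
  if (match_range(2, 7) && hasA1) return("7mer-A1")
  if (match_range(3, 8)) return("offset-6mer")
  if (match_range(2, 7)) return("6mer")
  "seedless"
}
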
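# Independent oracles used across the test files.
#
# enumerate_structures(): exhaustive recursion over every admissible nested
# structure (allowed pairs, minimum hairpin loop). Energies are computed
# compositionally from the model tables -- a different algorithm from the
# package's dynamic program -- tracking, per candidate structure, the summed
# energy of its closed branches plus enough exposed-level bookkeeping
# (branch count, unpaired count, outermost branch ends) to assign the loop
# term at each closure.

oracle_model_env <- function(model) {
  list(
    stack = model$stack,
    ml = model$multiloop,
    pairable = function(ci, cj) {
      key <- paste0(ci, cj)
      key %in% model$pair_levels
    },
    hp = function(sz) mirhairpin:::loop_penalty_centi(model, "hairpin", sz),
    bu = function(sz) mirhairpin:::loop_penalty_centi(model, "bulge", sz),
    il = function(sz) mirhairpin:::loop_penalty_centi(model, "internal", sz),
    min_hp = model$min_hairpin
  )
}

# returns data.frame(str, e, pairs) of ALL nested structures with exact
# integer centi-kcal energies
enumerate_structures <- function(sequence, model = energy_model()) {
  ch <- strsplit(toupper(gsub("T", "U", sequence)), "")[[1]]
  n <- length(ch)
  om <- oracle_model_env(model)
  memo <- new.env(parent = emptyenv())

  # recursive region [i, j]: data.frame with columns
  #   str, ecp (closed-branch energy), nb, nu, fb (first branch start, NA),
  #   lb (last branch end, NA), pairs
  region <- function(i, j) {
    if (i > j) {
      return(data.frame(str = "", ecp = 0L, nb = 0L, nu = 0L,
                        fb = NA_integer_, lb = NA_integer_, pairs = 0L))
    }
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    parts <- list()
    # case 1: i unpaired
    rest <- region(i + 1L, j)
    parts[[1]] <- data.frame(
      str = paste0(".", rest$str), ecp = rest$ecp, nb = rest$nb,
      nu = rest$nu + 1L, fb = rest$fb, lb = rest$lb, pairs = rest$pairs)
    # case 2: i paired with k
    for (k in seq2(i + om$min_hp + 1L, j)) {
      if (!om$pairable(ch[i], ch[k])) next
      inner <- region(i + 1L, k - 1L)
      # closure energy of (i, k) over each inner configuration
      closed <- closure_energy(i, k, inner, om, ch)
      keep <- which(!is.na(closed$e))
      if (!length(keep)) next
      after <- region(k + 1L, j)
      for (a in keep) {
        parts[[length(parts) + 1L]] <- data.frame(
          str = paste0("(", inner$str[a], ")", after$str),
          ecp = closed$e[a] + after$ecp,
          nb = after$nb + 1L, nu = after$nu,
          fb = i, lb = ifelse(is.na(after$lb), k, after$lb),
          pairs = inner$pairs[a] + 1L + after$pairs)
      }
    }
    out <- do.call(rbind, parts)
    memo[[key]] <- out
    out
  }

  seq2 <- function(a, b) if (a > b) integer(0) else a:b

  res <- region(1L, n)
  data.frame(str = res$str, e = res$ecp, pairs = res$pairs,
             stringsAsFactors = FALSE)
}

# energy (centi-kcal) of closing pair (i, k) over inner configurations;
# NA when the closure is inadmissible
closure_energy <- function(i, k, inner, om, ch) {
  e <- rep(NA_integer_, nrow(inner))
  for (a in seq_len(nrow(inner))) {
    nb <- inner$nb[a]; nu <- inner$nu[a]
    if (nb == 0L) {
      if (nu < om$min_hp) next
      e[a] <- inner$ecp[a] + om$hp(nu)
    } else if (nb == 1L) {
      n1 <- inner$fb[a] - (i + 1L)
      n2 <- (k - 1L) - inner$lb[a]
      if (n1 == 0L && n2 == 0L) {
        inner_pair <- paste0(ch[inner$fb[a]], ch[inner$lb[a]])
        outer_pair <- paste0(ch[i], ch[k])
        e[a] <- inner$ecp[a] + om$stack[outer_pair, inner_pair]
      } else if (n1 == 0L || n2 == 0L) {
        e[a] <- inner$ecp[a] + om$bu(n1 + n2)
      } else {
        e[a] <- inner$ecp[a] + om$il(n1 + n2)
      }
    } else {
      e[a] <- inner$ecp[a] + om$ml[["offset"]] +
        om$ml[["branch"]] * (nb + 1L) + om$ml[["unpaired"]] * nu
    }
  }
  data.frame(e = e)
}

# the oracle's pick under the package's declared tie-break:
# min energy, then max pairs, then lexicographically smallest dot-bracket
oracle_best <- function(sequence, model = energy_model()) {
  all <- enumerate_structures(sequence, model)
  o <- order(all$e, -all$pairs, all$str)
  best <- all[o[1], ]  # the open chain is in the set, so best$e <= 0
  list(dotbracket = best$str, delta_g = best$e / 100, pairs = best$pairs)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
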
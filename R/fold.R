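#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Dynamic program over all nested (pseudoknot-free) structures under the
#' package's nearest-neighbor [energy_model()]. The open chain (no pairs,
#' 0 kcal/mol) is always admissible, so the reported free energy is never
#' positive. Among co-optimal structures the result is deterministic: the
#' structure with the most base pairs is preferred, then the
#' lexicographically smallest dot-bracket string.
#'
#' @param sequence RNA string over A/C/G/U (use [normalize_rna()] for DNA
#'   input).
#' @param model An [energy_model()].
#' @return A `fold_result`: list with `sequence`, `dotbracket`, `pair_table`
#'   (partner index per position, 0 = unpaired) and `delta_g` (kcal/mol).
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(sequence, model = energy_model()) {
  codes <- encode_rna(sequence)
  n <- length(codes)
  if (n < 1) stop("sequence must have length >= 1")
  res <- .fold_mfe_cpp(
    codes, pairtype_matrix(model$pair_levels),
    model$stack,
    loop_penalty_centi(model, "hairpin",
                       pmax(seq_len(max(n, 3L)), 3L)),
    loop_penalty_centi(model, "bulge", seq_len(model$max_interior)),
    loop_penalty_centi(model, "internal",
                       pmax(seq_len(model$max_interior), 2L)),
    model$multiloop[["offset"]], model$multiloop[["branch"]],
    model$multiloop[["unpaired"]], model$min_hairpin, model$max_interior
  )
  new_fold_result(toupper(gsub("T", "U", sequence)), res$dotbracket,
                  res$e_centi / 100)
}

new_fold_result <- function(sequence, dotbracket, delta_g) {
  structure(
    list(sequence = sequence, dotbracket = dotbracket,
         pair_table = dotbracket_to_pairs(dotbracket), delta_g = delta_g),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> ", nchar(x$sequence), " nt, dG = ",
      sprintf("%.2f", x$delta_g), " kcal/mol\n", sep = "")
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n")
  invisible(x)
}

#' @rdname fold_mfe
#' @param x A `fold_result`.
#' @param ... Unused.
#' @return For `tidy()`: a tibble with one row per position (`pos`, `base`,
#'   `partner`, `paired`).
#' @export
tidy.fold_result <- function(x, ...) {
  tibble::tibble(
    pos = seq_along(x$pair_table),
    base = strsplit(x$sequence, "")[[1]],
    partner = x$pair_table,
    paired = x$pair_table > 0L
  )
}

#' @rdname fold_mfe
#' @return For `glance()`: a one-row tibble with `length`, `n_pairs`,
#'   `delta_g` and `dotbracket`.
#' @export
glance.fold_result <- function(x, ...) {
  tibble::tibble(
    length = nchar(x$sequence),
    n_pairs = sum(x$pair_table > 0L) %/% 2L,
    delta_g = x$delta_g,
    dotbracket = x$dotbracket
  )
}

#' Convert a dot-bracket string to a pair table
#'
#' @param dotbracket String over `(`, `)`, `.`.
#' @return Integer vector: partner index per position, 0 if unpaired.
#' @examples
#' dotbracket_to_pairs("((...))")
#' @export
dotbracket_to_pairs <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  if (!all(ch %in% c("(", ")", "."))) {
    stop("dot-bracket contains characters other than '(', ')', '.'")
  }
  pt <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket: unmatched '('")
  pt
}

#' Loop decomposition of a secondary structure
#'
#' Breaks a structure into its energy terms: one stack, hairpin, bulge,
#' interior, or multiloop term per closing pair. Each term records the set of
#' nucleotide positions that participate in it (both strands of closing and
#' inner pairs included), which is what region-restricted energies are
#' defined over. Exterior-loop bases carry no term.
#'
#' @inheritParams fold_mfe
#' @param dotbracket Structure for `sequence`, same length.
#' @return A tibble with columns `term`, `i`, `j` (closing pair), `size`,
#'   `energy` (kcal/mol) and a list-column `positions`.
#' @examples
#' decompose_structure("GGGAAAACCC", "(((....)))")
#' @export
decompose_structure <- function(sequence, dotbracket, model = energy_model()) {
  codes <- encode_rna(sequence)
  n <- length(codes)
  if (nchar(dotbracket) != n) stop("structure length != sequence length")
  pt <- dotbracket_to_pairs(dotbracket)
  ptype <- pairtype_matrix(model$pair_levels)

  pair_id <- function(i, j) {
    id <- ptype[codes[i] + 1L, codes[j] + 1L]
    if (id < 0) {
      stop("disallowed pair ", substr(sequence, i, i),
           "-", substr(sequence, j, j), " at (", i, ",", j, ")")
    }
    id + 1L
  }

  terms <- list()
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j <= i) next
    pair_id(i, j)  # validates
    # walk the loop closed by (i, j)
    children <- list()
    unpaired <- integer(0)
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        children[[length(children) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else if (pt[k] == 0L) {
        unpaired <- c(unpaired, k)
        k <- k + 1L
      } else {
        stop("crossing pairs in structure")  # unreachable for stack-parsed pt
      }
    }
    nb <- length(children)
    if (nb == 0L) {
      size <- j - i - 1L
      if (size < model$min_hairpin) {
        stop("hairpin loop of size ", size, " below the model minimum")
      }
      terms[[length(terms) + 1L]] <- list(
        term = "hairpin", i = i, j = j, size = size,
        e = loop_penalty_centi(model, "hairpin", size), pos = i:j)
    } else if (nb == 1L) {
      k1 <- children[[1]][1]; l1 <- children[[1]][2]
      n1 <- k1 - i - 1L; n2 <- j - l1 - 1L
      if (n1 == 0L && n2 == 0L) {
        terms[[length(terms) + 1L]] <- list(
          term = "stack", i = i, j = j, size = 0L,
          e = model$stack[pair_id(i, j), pair_id(k1, l1)],
          pos = c(i, k1, l1, j))
      } else if (n1 == 0L || n2 == 0L) {
        terms[[length(terms) + 1L]] <- list(
          term = "bulge", i = i, j = j, size = n1 + n2,
          e = loop_penalty_centi(model, "bulge", n1 + n2),
          pos = c(i:k1, l1:j))
      } else {
        terms[[length(terms) + 1L]] <- list(
          term = "internal", i = i, j = j, size = n1 + n2,
          e = loop_penalty_centi(model, "internal", n1 + n2),
          pos = c(i:k1, l1:j))
      }
    } else {
      e <- model$multiloop[["offset"]] +
        model$multiloop[["branch"]] * (nb + 1L) +
        model$multiloop[["unpaired"]] * length(unpaired)
      terms[[length(terms) + 1L]] <- list(
        term = "multiloop", i = i, j = j, size = length(unpaired),
        e = e, pos = sort(c(i, j, unpaired, unlist(children))))
    }
  }

  tibble::new_tibble(list(
    term = vapply(terms, function(t) t$term, character(1)),
    i = vapply(terms, function(t) t$i, integer(1)),
    j = vapply(terms, function(t) t$j, integer(1)),
    size = vapply(terms, function(t) as.integer(t$size), integer(1)),
    energy = vapply(terms, function(t) t$e / 100, numeric(1)),
    positions = lapply(terms, function(t) t$pos)
  ), nrow = length(terms))
}

#' Free energy of a given structure
#'
#' Sum of the loop-decomposition terms of `dotbracket` under `model`.
#' `evaluate_structure_energy(s, fold_mfe(s)$dotbracket)` equals
#' `fold_mfe(s)$delta_g` exactly.
#'
#' @inheritParams decompose_structure
#' @return Free energy in kcal/mol.
#' @export
evaluate_structure_energy <- function(sequence, dotbracket,
                                      model = energy_model()) {
  sum_kcal(decompose_structure(sequence, dotbracket, model)$energy)
}

#' Free energy restricted to a region
#'
#' Sums the energy terms of the loop decomposition whose participating
#' nucleotides all lie inside `region`. Terms straddling the region boundary
#' are attributed to no region, so region energies over a tiling of the
#' molecule sum to at most the total (and to exactly the total when region
#' boundaries follow decomposition boundaries). With `region` covering the
#' whole molecule the result is the total free energy.
#'
#' @inheritParams decompose_structure
#' @param region Integer vector of 1-based positions (need not be contiguous;
#'   a two-arm region is typical).
#' @return Free energy in kcal/mol of the fully-contained terms.
#' @examples
#' region_energy("GGGAAAACCC", "(((....)))", 1:10)
#' @export
region_energy <- function(sequence, dotbracket, region,
                          model = energy_model()) {
  n <- nchar(sequence)
  region <- as.integer(region)
  if (length(region) && (min(region) < 1L || max(region) > n)) {
    stop("region positions outside sequence bounds")
  }
  dec <- decompose_structure(sequence, dotbracket, model)
  if (!nrow(dec)) return(0)
  inside <- vapply(dec$positions, function(p) all(p %in% region), logical(1))
  sum_kcal(dec$energy[inside])
}

# energies are exact multiples of 0.01; summing in centi-kcal keeps
# folded and re-evaluated values identical to the last bit
sum_kcal <- function(kcal) {
  sum(as.integer(round(100 * kcal))) / 100
}

#' Write and read single-record dot-bracket files
#'
#' Plain-text dot-bracket format: an id line (`>id`), the sequence line, and
#' the structure line with the free energy appended in parentheses.
#'
#' @param fold A `fold_result`.
#' @param id Record identifier.
#' @param path File path.
#' @return `read_dotbracket()` returns a `fold_result` with an `id` attribute.
#' @export
write_dotbracket <- function(fold, id, path) {
  writeLines(c(
    paste0(">", id),
    fold$sequence,
    sprintf("%s (%.2f)", fold$dotbracket, fold$delta_g)
  ), path)
  invisible(path)
}

#' @rdname write_dotbracket
#' @export
read_dotbracket <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 3 || !startsWith(ln[1], ">")) {
    stop("not a dot-bracket record file: ", path)
  }
  m <- regmatches(ln[3], regexec("^([().]+) \\((-?[0-9.]+)\\)$", ln[3]))[[1]]
  if (!length(m)) stop("malformed structure line in ", path)
  out <- new_fold_result(ln[2], m[2], as.numeric(m[3]))
  attr(out, "id") <- substring(ln[1], 2)
  out
}

# ---- sequence helpers ----

#' Normalize a nucleic-acid string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any other non-ACGU character is an error.
#'
#' @param x Character vector of sequences.
#' @return Character vector over A/C/G/U.
#' @export
normalize_rna <- function(x) {
  x <- gsub("T", "U", toupper(x))
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("sequence contains non-ACGU(T) characters: ",
         paste(substr(x[bad], 1, 20), collapse = ", "))
  }
  x
}

# 0-based codes A=0 C=1 G=2 U=3; hard error on anything else
encode_rna <- function(sequence) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  ch <- strsplit(normalize_rna(sequence), "")[[1]]
  match(ch, c("A", "C", "G", "U")) - 1L
}

# 4x4 matrix over base codes -> 0-based pair-type index into pair_levels,
# -1 for disallowed pairs
pairtype_matrix <- function(pair_levels) {
  bases <- c("A", "C", "G", "U")
  m <- matrix(-1L, 4, 4)
  for (p in seq_along(pair_levels)) {
    i <- match(substr(pair_levels[p], 1, 1), bases)
    j <- match(substr(pair_levels[p], 2, 2), bases)
    m[i, j] <- p - 1L
  }
  m
}
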
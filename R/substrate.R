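#' Design a pri-miRNA transcription substrate
#'
#' Extracts the pre-miRNA plus flanking sequence from its genomic context:
#' by default 30 extra nt 5' and 40 nt 3' of the pre-miRNA, the extensions
#' needed for Drosha processing. Flanks are clipped (with a warning) when
#' the supplied context is shorter than requested.
#'
#' @param genomic_context Sequence containing the pre-miRNA (DNA or RNA;
#'   normalized to RNA).
#' @param pre_span `c(start, end)` of the pre-miRNA within
#'   `genomic_context`, 1-based inclusive.
#' @param flank5,flank3 Requested flank lengths in nt.
#' @param id Substrate identifier.
#' @return A `substrate_design`: list with `id`, `rna`, `edits` (empty
#'   tibble), realized `flank5`/`flank3`, and the pre-miRNA span within the
#'   substrate (`pre_local`).
#' @export
design_pri_substrate <- function(genomic_context, pre_span, flank5 = 30L,
                                 flank3 = 40L, id = "substrate") {
  ctx <- normalize_rna(genomic_context)
  n <- nchar(ctx)
  pre_span <- as.integer(pre_span)
  if (pre_span[1] < 1L || pre_span[2] > n || pre_span[1] > pre_span[2]) {
    stop("pre_span outside the genomic context")
  }
  f5 <- min(flank5, pre_span[1] - 1L)
  f3 <- min(flank3, n - pre_span[2])
  if (f5 < flank5 || f3 < flank3) {
    warning("genomic context shorter than requested flanks; clipped to ",
            f5, "/", f3, " nt", call. = FALSE)
  }
  rna <- substr(ctx, pre_span[1] - f5, pre_span[2] + f3)
  structure(
    list(id = id, rna = rna,
         edits = tibble::tibble(position = integer(0), from = character(0),
                                to = character(0)),
         flank5 = f5, flank3 = f3,
         pre_local = c(f5 + 1L, f5 + pre_span[2] - pre_span[1] + 1L)),
    class = "substrate_design"
  )
}

#' Design a pre-miRNA T7 transcription substrate
#'
#' T7 RNA polymerase initiates on G, so a pre-miRNA whose 5' end is not G
#' gets its first residue changed to G; when that position is paired in the
#' predicted structure, the pairing partner is changed to C so the predicted
#' secondary structure is maintained. The edited substrate is refolded and
#' the design records whether the position-1 pair survived. The operation is
#' idempotent: a substrate already starting with G is returned unedited.
#'
#' @param pre_rna Pre-miRNA sequence.
#' @param pre_fold Optional [fold_mfe()] result for `pre_rna` (computed if
#'   missing).
#' @param model An [energy_model()].
#' @param id Substrate identifier.
#' @return A `substrate_design` with `rna`, `edits`
#'   (`position`/`from`/`to`), and `pair1_preserved`: `TRUE` when position 1
#'   has the same partner before and after editing (vacuously `TRUE` for
#'   unedited or originally-unpaired substrates).
#' @export
design_pre_substrate <- function(pre_rna, pre_fold = NULL,
                                 model = energy_model(), id = "substrate") {
  rna <- normalize_rna(pre_rna)
  edits <- tibble::tibble(position = integer(0), from = character(0),
                          to = character(0))
  first <- substr(rna, 1, 1)
  if (first == "G") {
    return(structure(list(id = id, rna = rna, edits = edits,
                          pair1_preserved = TRUE),
                     class = "substrate_design"))
  }
  pre_fold <- pre_fold %||% fold_mfe(rna, model)
  partner <- pre_fold$pair_table[1]
  ch <- strsplit(rna, "")[[1]]
  edits <- tibble::add_row(edits, position = 1L, from = first, to = "G")
  ch[1] <- "G"
  if (partner > 0L) {
    edits <- tibble::add_row(edits, position = partner,
                             from = ch[partner], to = "C")
    ch[partner] <- "C"
  }
  out <- paste(ch, collapse = "")
  refold <- fold_mfe(out, model)
  preserved <- if (partner > 0L) refold$pair_table[1] == partner else TRUE
  structure(list(id = id, rna = out, edits = edits,
                 pair1_preserved = preserved),
            class = "substrate_design")
}

#' @export
print.substrate_design <- function(x, ...) {
  cat("<substrate_design>", x$id, "-", nchar(x$rna), "nt,",
      nrow(x$edits), "edit(s)\n")
  if (nrow(x$edits)) print(x$edits)
  invisible(x)
}
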
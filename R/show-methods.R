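setMethod("show", "CircularGenome", function(object) {
  cat(sprintf("CircularGenome '%s': %d bp, %s, %s\n", object@id,
              object@length,
              if (object@circular) "circular" else "linear",
              if (length(object@seq)) "sequence present"
              else "feature-table-only (no sequence)"))
})

setMethod("show", "ArchitectureReport", function(object) {
  t <- object@totals
  cat(sprintf(
    "ArchitectureReport (%d bp circle)\n  overlaps:    %d (%d bp)\n  spacers:     %d (%d bp)\n  adjacencies: %d\n",
    object@genomeLength, t[["overlap_count"]], t[["overlap_bp"]],
    t[["spacer_count"]], t[["spacer_bp"]], t[["adjacency_count"]]))
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "CodonUsageTable", function(object) {
  cat(sprintf("CodonUsageTable: %d codons counted, %s families, RSCU %s\n",
              sum(object@counts), object@familyMode,
              if (all(is.na(object@rscu))) "unset" else "computed"))
})

setMethod("show", "CloverleafFold", function(object) {
  cls <- table(factor(object@pairs$class, c("WC", "GU", "mismatch")))
  cat(sprintf(
    "CloverleafFold%s: score %g; %d pairs (%d WC, %d G-U, %d mismatch); anticodon %s\n",
    if (nzchar(object@trna)) paste0(" ", object@trna) else "",
    object@foldScore, nrow(object@pairs), cls[["WC"]], cls[["GU"]],
    cls[["mismatch"]], object@anticodonTriplet))
})

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix: %d taxa x %d columns, %d partitions (%s...)\n",
              length(object@taxa), nchar(object@sequences[1]),
              nrow(object@partitions),
              paste(head(object@partitions$gene, 3), collapse = ", ")))
})

setMethod("show", "MitoGenomeSpec", function(object) {
  cat(sprintf(
    "MitoGenomeSpec: %d bp circle, %d genes (%s)\n", object@genomeLength,
    nrow(object@genes),
    paste(sprintf("%d %s", table(object@genes$class),
                  names(table(object@genes$class))), collapse = ", ")))
})
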
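#' Per-species conservation call for a retro-miR sequence
#'
#' Identity is computed from a global alignment with terminal gap columns
#' excluded (so a truncated ortholog is not penalized for missing ends);
#' a species is conserved when identity is strictly greater than
#' `threshold`. Species missing from the panel are reported as absent
#' (NA identity, not conserved).
#'
#' @param retromir_seq The human retro-miR (precursor) sequence.
#' @param panel Named list/character vector of ortholog sequences; names
#'   are species drawn from `species_order`.
#' @param species_order Ordered species vector, closest relative first.
#' @param threshold Strict identity threshold (default 0.80).
#' @return A `conservation_call`: data frame with `species`, `identity`,
#'   `conserved`, `present`.
#' @export
call_conservation <- function(retromir_seq, panel,
                              species_order = c("chimpanzee", "gorilla",
                                                "orangutan", "rhesus",
                                                "marmoset"),
                              threshold = 0.80) {
  rows <- lapply(species_order, function(sp) {
    if (is.null(panel) || !sp %in% names(panel) ||
        is.na(panel[[sp]]) || !nzchar(panel[[sp]])) {
      return(data.frame(species = sp, identity = NA_real_,
                        conserved = FALSE, present = FALSE,
                        stringsAsFactors = FALSE))
    }
    aln <- align_global(retromir_seq, panel[[sp]])
    ident <- alignment_identity(aln, exclude_end_gaps = TRUE)
    data.frame(species = sp, identity = ident,
               conserved = !is.na(ident) && ident > threshold,
               present = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("conservation_call", class(out))
  out
}

#' Assign an evolutionary age from a conservation call
#'
#' The age is the most distal species (along `species_order`) in which
#' the sequence is conserved: no conserved species gives
#' `"human-specific"`, conservation out to the last species gives
#' `"all primates"`, and otherwise the label is `"human-to-<species>"`.
#'
#' @param call A `conservation_call` from [call_conservation()].
#' @param species_order Ordered species vector (must match the call).
#' @return Character age label.
#' @export
assign_age <- function(call, species_order = call$species) {
  call <- call[match(species_order, call$species), , drop = FALSE]
  idx <- which(call$conserved)
  if (length(idx) == 0) return("human-specific")
  most_distal <- max(idx)
  if (most_distal == length(species_order)) return("all primates")
  paste0("human-to-", species_order[most_distal])
}
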
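#' Backbone specification for artificial mirtron hairpins
#'
#' The backbone fixes everything about a hairpin except the guide: the loop
#' sequence, how many guide 3'-terminal positions must stay Watson-Crick
#' paired (RISC strand-bias rule), and the width of the polypyrimidine
#' window edited on the passenger. The packaged default uses the widely used
#' miR-30-style loop as a synthetic stand-in; published mirtron backbones can
#' be substituted by passing their loop.
#'
#' @param loop Loop sequence (>= 3 nt).
#' @param name Label carried into reports.
#' @param wc_protect_guide3 Number of guide 3'-terminal positions kept
#'   Watson-Crick paired (default 4).
#' @param ppt_window Width of the pre-acceptor polypyrimidine window edited
#'   on the passenger (default 10 nt).
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(loop = "TAGTGAAGCCACAGATGTA",
                          name = "miR30-loop-synthetic",
                          wc_protect_guide3 = 4,
                          ppt_window = 10) {
  loop <- dna(loop)
  if (nchar(loop) < 3) abort("backbone loop must be at least 3 nt")
  structure(list(loop = loop, name = name,
                 wc_protect_guide3 = as.integer(wc_protect_guide3),
                 ppt_window = as.integer(ppt_window)),
            class = "backbone_spec")
}

pair_class <- function(b5, b3) {
  wc <- c(AT = TRUE, TA = TRUE, GC = TRUE, CG = TRUE)
  gu <- c(GT = TRUE, TG = TRUE)
  key <- paste0(b5, b3)
  dplyr::case_when(
    !is.na(wc[key]) ~ "WC",
    !is.na(gu[key]) ~ "GU",
    TRUE ~ "mismatch"
  )
}

#' Edit a passenger strand for splicing and strand bias
#'
#' Starting from the full reverse complement of the guide, the passenger is
#' edited so the assembled intron satisfies splicing and RISC-loading rules:
#'
#' * the splice-site terminus carried by the passenger is enforced (intron
#'   must end AG when the guide is the 5' arm, begin GT when it is the 3'
#'   arm), accepting a terminal mismatch where unavoidable;
#' * when the passenger carries the intron 3' region (5'-arm guide), purines
#'   in the pre-acceptor polypyrimidine window are converted to T wherever
#'   the resulting non-Watson-Crick pair is permitted, i.e. outside the
#'   protected guide 3'-terminal block;
#' * the guide's 3'-terminal `wc_protect_guide3` positions are kept
#'   Watson-Crick paired so the guide, not the passenger, is loaded into
#'   RISC; conflicts are reported as warnings, never silently resolved.
#'
#' @param guide Guide sequence (5'-arm guides start GT; 3'-arm guides end AG).
#' @param arm `"5p"` or `"3p"`: which hairpin arm the guide occupies.
#' @param backbone A [backbone_spec()].
#' @return List with `passenger`, `edits` (tibble: passenger position, old,
#'   new, reason) and `warnings` (character).
#' @export
design_passenger <- function(guide, arm = c("5p", "3p"),
                             backbone = backbone_spec()) {
  arm <- match.arg(arm)
  guide <- dna(guide)
  L <- nchar(guide)
  check_arm_rule(guide, arm)
  g <- strsplit(guide, "")[[1]]
  p <- strsplit(revcomp(guide), "")[[1]]
  edits <- list()
  warnings <- character()
  log_edit <- function(pos, old, new, reason) {
    tibble(position = as.integer(pos), old = old, new = new, reason = reason)
  }
  # guide 3'-terminal protected positions always pair passenger 5' positions 1..k
  protect_pass <- seq_len(min(backbone$wc_protect_guide3, L))

  if (arm == "5p") {
    # passenger is the 3' arm; intron must end ...AG
    if (p[L] != "G") {
      edits <- c(edits, list(log_edit(L, p[L], "G", "acceptor AG terminus")))
      p[L] <- "G"
    }
    if (p[L - 1] != "A") {
      edits <- c(edits, list(log_edit(L - 1, p[L - 1], "A", "acceptor AG terminus")))
      p[L - 1] <- "A"
    }
    # polypyrimidine window: 10 nt immediately 5' of the terminal NAG
    win <- seq(L - 2 - backbone$ppt_window, L - 3)
    win <- win[win >= 1]
    for (i in win) {
      if (p[i] %in% c("A", "G")) {
        gi <- L - i + 1 # guide partner (guide is 5' arm)
        if (i %in% protect_pass || gi > L - backbone$wc_protect_guide3) {
          warnings <- c(warnings, sprintf(
            "purine at passenger position %d left in tract: position is WC-protected", i))
        } else {
          edits <- c(edits, list(log_edit(i, p[i], "T", "polypyrimidine tract")))
          p[i] <- "T"
        }
      }
    }
  } else {
    # passenger is the 5' arm; intron must begin GT...
    if (p[1] != "G") {
      edits <- c(edits, list(log_edit(1, p[1], "G", "donor GT terminus")))
      p[1] <- "G"
    }
    if (p[2] != "T") {
      edits <- c(edits, list(log_edit(2, p[2], "T", "donor GT terminus")))
      p[2] <- "T"
    }
  }
  # verify the strand-bias contract: guide 3' terminal block WC-paired
  for (k in protect_pass) {
    gi <- L - k + 1
    cls <- if (arm == "5p") pair_class(g[gi], p[k]) else pair_class(p[k], g[gi])
    if (cls != "WC") {
      warnings <- c(warnings, sprintf(
        "guide 3'-terminal position %d is %s-paired (splice-site constraint overrides WC rule)",
        gi, cls))
    }
  }
  list(
    passenger = paste(p, collapse = ""),
    edits = if (length(edits)) bind_rows(edits) else
      tibble(position = integer(), old = character(),
             new = character(), reason = character()),
    warnings = warnings
  )
}

#' Assemble an artificial mirtron hairpin around a guide strand
#'
#' Builds the full intron `5' arm + loop + 3' arm` with the guide on the
#' requested arm and a passenger designed by [design_passenger()]. The
#' resulting intron begins GT and ends AG (the defining property of a
#' mirtron: splice sites delimit the pre-miRNA), both arms have the guide's
#' length, and the pairing layout plus nearest-neighbor free energy are
#' attached.
#'
#' @inheritParams design_passenger
#' @return A `mirtron_hairpin` object: list with `arm5`, `loop`, `arm3`,
#'   `guide`, `guide_arm`, `pairing` (tibble: `i5`, `i3`, `base5`, `base3`,
#'   `class`), `thermo` (see [pairing_delta_g()]), `edits`, `warnings`,
#'   `backbone`.
#' @examples
#' hp <- build_hairpin("GTAAGTACGCATTCAGCCAAC", arm = "5p")
#' glance(hp)
#' @export
build_hairpin <- function(guide, arm = c("5p", "3p"),
                          backbone = backbone_spec()) {
  arm <- match.arg(arm)
  guide <- dna(guide)
  des <- design_passenger(guide, arm, backbone)
  if (arm == "5p") {
    arm5 <- guide; arm3 <- des$passenger
  } else {
    arm5 <- des$passenger; arm3 <- guide
  }
  hp <- new_hairpin(arm5, backbone$loop, arm3, guide = guide, guide_arm = arm,
                    backbone = backbone, edits = des$edits,
                    warnings = des$warnings)
  intron <- hairpin_intron(hp)
  if (str_sub(intron, 1, 2) != "GT" || str_sub(intron, -2, -1) != "AG") {
    abort("internal design failure: intron is not GT...AG")
  }
  hp
}

new_hairpin <- function(arm5, loop, arm3, guide, guide_arm, backbone,
                        edits = NULL, warnings = character(),
                        unspliceable = FALSE) {
  L5 <- nchar(arm5); L3 <- nchar(arm3)
  stopifnot(L5 == L3)
  b5 <- strsplit(arm5, "")[[1]]
  b3 <- strsplit(arm3, "")[[1]]
  pairing <- tibble(
    i5 = seq_len(L5),
    i3 = rev(seq_len(L3)),
    base5 = b5,
    base3 = b3[rev(seq_len(L3))],
    class = pair_class(b5, b3[rev(seq_len(L3))])
  )
  hp <- structure(list(
    arm5 = arm5, loop = loop, arm3 = arm3,
    guide = guide, guide_arm = guide_arm,
    pairing = pairing,
    backbone = backbone,
    edits = edits,
    warnings = warnings,
    unspliceable = unspliceable
  ), class = "mirtron_hairpin")
  hp$thermo <- pairing_delta_g(hp)
  hp
}

#' Full intron sequence of a hairpin
#' @param hairpin A `mirtron_hairpin`.
#' @return DNA string `arm5 + loop + arm3`.
#' @export
hairpin_intron <- function(hairpin) {
  paste0(hairpin$arm5, hairpin$loop, hairpin$arm3)
}

#' Extract the guide arm sequence from a hairpin
#' @param hairpin A `mirtron_hairpin`.
#' @return The sequence currently on the guide-designated arm.
#' @export
hairpin_guide_arm <- function(hairpin) {
  if (hairpin$guide_arm == "5p") hairpin$arm5 else hairpin$arm3
}

check_arm_rule <- function(guide, arm) {
  if (arm == "5p" && str_sub(guide, 1, 2) != "GT") {
    abort(sprintf("5'-arm guide must start GT to form the splice donor (got %s...)",
                  str_sub(guide, 1, 2)))
  }
  if (arm == "3p" && str_sub(guide, -2, -1) != "AG") {
    abort(sprintf("3'-arm guide must end AG to form the splice acceptor (got ...%s)",
                  str_sub(guide, -2, -1)))
  }
  invisible(TRUE)
}

# Turner-style RNA nearest-neighbor stack free energies (kcal/mol, 37 C) for
# Watson-Crick stacks, indexed pair(i) -> pair(i+1) walking 5'->3' along the
# 5' arm. Pairs written as (arm5 base, arm3 base) in RNA letters.
NN_STACK <- c(
  "AU.AU" = -0.93, "AU.UA" = -1.10, "AU.GC" = -2.08, "AU.CG" = -2.24,
  "UA.AU" = -1.33, "UA.UA" = -0.93, "UA.GC" = -2.11, "UA.CG" = -2.35,
  "GC.AU" = -2.35, "GC.UA" = -2.24, "GC.GC" = -3.26, "GC.CG" = -3.42,
  "CG.AU" = -2.11, "CG.UA" = -2.08, "CG.GC" = -2.36, "CG.CG" = -3.26
)
GU_STACK_DG <- -0.5   # flat value for any stack containing a G-U wobble
MISMATCH_DG <- 0.8    # destabilisation per internal mismatch
HAIRPIN_LOOP_DG <- 5.6 # closing-loop initiation term

#' Nearest-neighbor free energy of a designed hairpin pairing layout
#'
#' Deterministic free-energy estimate over the *designed* pairing (the
#' layout is engineered, not predicted): Watson-Crick stacks use a Turner-
#' style nearest-neighbor table, any stack containing a G-U wobble gets a
#' flat weak value, each mismatch adds a fixed penalty and interrupts
#' stacking, and a constant hairpin-loop term closes the stem. Less negative
#' values mean a less stable hairpin.
#'
#' @param hairpin A `mirtron_hairpin` object.
#' @return List with `delta_g` (kcal/mol), `dg_guide5_end` and
#'   `dg_guide3_end` (stack sums over the terminal four pairs at each end of
#'   the guide), and pair-class counts `n_wc`, `n_gu`, `n_mismatch`.
#' @export
pairing_delta_g <- function(hairpin) {
  pr <- hairpin$pairing
  rna5 <- chartr("T", "U", pr$base5)
  rna3 <- chartr("T", "U", pr$base3)
  pair_id <- paste0(rna5, rna3)
  paired <- pr$class %in% c("WC", "GU")
  n <- nrow(pr)
  stack_dg <- numeric(max(n - 1, 0))
  for (i in seq_len(max(n - 1, 0))) {
    if (paired[i] && paired[i + 1]) {
      stack_dg[i] <- if (pr$class[i] == "WC" && pr$class[i + 1] == "WC") {
        unname(NN_STACK[paste0(pair_id[i], ".", pair_id[i + 1])])
      } else {
        GU_STACK_DG
      }
    }
  }
  mism <- sum(pr$class == "mismatch") * MISMATCH_DG
  terminal_window <- function(idx) {
    idx <- idx[idx >= 1 & idx <= n - 1]
    sum(stack_dg[idx]) + sum(pr$class[unique(c(idx, idx + 1))] == "mismatch") * MISMATCH_DG
  }
  # stacks among the terminal 4 guide positions at each end
  if (hairpin$guide_arm == "5p") {
    g5_idx <- 1:3; g3_idx <- (n - 3):(n - 1)
  } else {
    # guide is arm3: its 5' end pairs the arm5 3' end (high i5), 3' end low i5
    g5_idx <- (n - 3):(n - 1); g3_idx <- 1:3
  }
  list(
    delta_g = HAIRPIN_LOOP_DG + sum(stack_dg) + mism,
    dg_guide5_end = terminal_window(g5_idx),
    dg_guide3_end = terminal_window(g3_idx),
    n_wc = sum(pr$class == "WC"),
    n_gu = sum(pr$class == "GU"),
    n_mismatch = sum(pr$class == "mismatch")
  )
}

#' Destabilise a hairpin by passenger-strand substitutions
#'
#' Generates variants with less negative folding energy by converting
#' Watson-Crick pairs to mismatches via passenger-only substitutions (the
#' guide never changes), mirroring the strategy of weakening an over-paired
#' hairpin to improve its splicing. Substitutions avoid the splice-site
#' termini, the protected guide 3'-terminal block and (for 5'-arm guides)
#' the polypyrimidine window. Candidate positions are ranked by how much
#' each substitution raises the free energy; variant `k` applies the top `k`.
#'
#' @param hairpin A `mirtron_hairpin`.
#' @param n_substitutions Integer vector: how many substitutions each variant
#'   carries (default `1:2`). `0` returns the original hairpin.
#' @param positions Optional explicit passenger positions to substitute,
#'   overriding automatic choice; one variant is returned applying all.
#' @return List of `mirtron_hairpin` variants sorted by ascending `delta_g`
#'   (most stable first); each satisfies
#'   `delta_g(variant) > delta_g(original)` unless it is the 0-substitution
#'   original.
#' @export
destabilize <- function(hairpin, n_substitutions = 1:2, positions = NULL) {
  L <- nchar(hairpin$guide)
  pass_is_5 <- hairpin$guide_arm == "3p"
  editable <- editable_passenger_positions(hairpin)
  apply_subs <- function(pos) {
    p <- strsplit(if (pass_is_5) hairpin$arm5 else hairpin$arm3, "")[[1]]
    g <- strsplit(hairpin$guide, "")[[1]]
    for (i in pos) {
      gi <- L - i + 1
      p[i] <- g[gi] # same base as the partner: guaranteed mismatch, never G-U
    }
    pass <- paste(p, collapse = "")
    if (pass_is_5) {
      new_hairpin(pass, hairpin$loop, hairpin$arm3, hairpin$guide, "3p",
                  hairpin$backbone, hairpin$edits, hairpin$warnings)
    } else {
      new_hairpin(hairpin$arm5, hairpin$loop, pass, hairpin$guide, "5p",
                  hairpin$backbone, hairpin$edits, hairpin$warnings)
    }
  }
  if (!is.null(positions)) {
    bad <- setdiff(positions, editable)
    if (length(bad)) {
      abort(sprintf("passenger position(s) %s are not editable",
                    paste(bad, collapse = ", ")))
    }
    return(list(apply_subs(positions)))
  }
  if (max(n_substitutions) > length(editable)) {
    abort(sprintf("requested %d substitutions but only %d editable passenger positions",
                  max(n_substitutions), length(editable)))
  }
  # rank single substitutions by free-energy gain
  gain <- map_dbl(editable, function(i) {
    apply_subs(i)$thermo$delta_g - hairpin$thermo$delta_g
  })
  ranked <- editable[order(-gain, editable)]
  variants <- map(sort(unique(n_substitutions)), function(k) {
    if (k == 0) hairpin else apply_subs(ranked[seq_len(k)])
  })
  variants[order(map_dbl(variants, ~ .x$thermo$delta_g))]
}

# passenger positions where a WC pair may be broken without touching splice
# termini, the protected guide 3' block, or the polypyrimidine window
editable_passenger_positions <- function(hairpin) {
  L <- nchar(hairpin$guide)
  bk <- hairpin$backbone
  pass_is_5 <- hairpin$guide_arm == "3p"
  pr <- hairpin$pairing
  # passenger index -> pairing row
  if (pass_is_5) {
    wc_at <- function(i) pr$class[pr$i5 == i] == "WC"
  } else {
    wc_at <- function(i) pr$class[pr$i3 == i] == "WC"
  }
  blocked <- seq_len(min(bk$wc_protect_guide3, L)) # partners of guide 3' block
  if (pass_is_5) {
    blocked <- c(blocked, 1:2) # donor GT
  } else {
    blocked <- c(blocked, L - 1, L) # acceptor AG
    ppt <- seq(L - 2 - bk$ppt_window, L - 3)
    blocked <- c(blocked, ppt[ppt >= 1])
  }
  cand <- setdiff(seq_len(L), blocked)
  cand[vapply(cand, wc_at, logical(1))]
}

#' Make an unspliceable (US) control variant
#'
#' A single G-to-A substitution within the donor hexamer (intron positions
#' 1-6) abolishes spliceosome recognition while leaving the rest of the
#' hairpin, and hence any splicing-independent processing, untouched. The
#' default hits the +1 G of the invariant GT. The output differs from the
#' input intron at exactly one position.
#'
#' @param hairpin A `mirtron_hairpin`.
#' @param position Intron position (1-6) of the G to substitute; default 1.
#' @return A `mirtron_hairpin` flagged `unspliceable`.
#' @export
make_unspliceable <- function(hairpin, position = NULL) {
  intron <- hairpin_intron(hairpin)
  donor <- str_sub(intron, 1, 6)
  if (is.null(position)) {
    if (!str_detect(donor, "G")) abort("no G in the donor hexamer to substitute")
    # default: the +1 G of the invariant GT, else the first donor G
    gs <- which(strsplit(donor, "")[[1]] == "G")
    position <- gs[1]
  }
  if (position < 1 || position > 6) abort("US substitution must lie in intron positions 1-6")
  if (substr(intron, position, position) != "G") {
    abort(sprintf("intron position %d is %s, not G",
                  position, substr(intron, position, position)))
  }
  arm5 <- hairpin$arm5
  substr(arm5, position, position) <- "A" # donor hexamer lies in the 5' arm
  new_hairpin(arm5, hairpin$loop, hairpin$arm3, hairpin$guide,
              hairpin$guide_arm, hairpin$backbone, hairpin$edits,
              c(hairpin$warnings,
                sprintf("unspliceable: G>A at intron position %d", position)),
              unspliceable = TRUE)
}

#' Convert a mirtron to its shRNA equivalent
#'
#' An shRNA expressing the same hairpin from a pol III promoter is obtained
#' by exchanging the final two intron nucleotides for a U6 termination motif.
#'
#' @param hairpin A `mirtron_hairpin`.
#' @param terminator Termination motif (default `"TTTTTT"`).
#' @return DNA string of length `intron length - 2 + nchar(terminator)`.
#' @export
to_shrna <- function(hairpin, terminator = "TTTTTT") {
  intron <- hairpin_intron(hairpin)
  if (nchar(intron) < 2) abort("intron shorter than 2 nt")
  if (nchar(terminator) > 0) terminator <- dna(terminator)
  paste0(str_sub(intron, 1, -3), terminator)
}

#' @export
print.mirtron_hairpin <- function(x, ...) {
  cat(sprintf("<mirtron_hairpin> guide on %s arm, %d nt intron%s\n",
              x$guide_arm, nchar(hairpin_intron(x)),
              if (isTRUE(x$unspliceable)) " [unspliceable]" else ""))
  cat(sprintf("  5' %s ... loop %s ... %s 3'\n", x$arm5, x$loop, x$arm3))
  cat(sprintf("  dG %.2f kcal/mol (%d WC, %d G-U, %d mismatch)\n",
              x$thermo$delta_g, x$thermo$n_wc, x$thermo$n_gu,
              x$thermo$n_mismatch))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mirtron_hairpin <- function(x, ...) x$pairing

#' @exportS3Method generics::glance
glance.mirtron_hairpin <- function(x, ...) {
  intron <- hairpin_intron(x)
  tibble(
    guide_arm = x$guide_arm,
    guide = x$guide,
    intron_length = nchar(intron),
    arm_length = nchar(x$arm5),
    donor_hexamer = str_sub(intron, 1, 6),
    acceptor_tail = str_sub(intron, -13, -1),
    delta_g = x$thermo$delta_g,
    dg_guide5_end = x$thermo$dg_guide5_end,
    dg_guide3_end = x$thermo$dg_guide3_end,
    n_wc = x$thermo$n_wc,
    n_gu = x$thermo$n_gu,
    n_mismatch = x$thermo$n_mismatch,
    unspliceable = isTRUE(x$unspliceable),
    n_warnings = length(x$warnings)
  )
}
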
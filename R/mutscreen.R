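#' Read a table of predicted mutation free-energy changes
#'
#' Ingests delimited text exported from stability/affinity predictors.
#' Columns are mapped by name onto the canonical record fields:
#' `position`, `wt_aa`, `mut_aa`, `ddG_F_monomer`, `ddG_F_dimer`,
#' `ddG_B`. The sign convention is positive = destabilizing. `ddG_B`
#' may be missing (`NA`).
#'
#' @param file Path to a delimited text file with a header row.
#' @param sep Field separator (default tab; `","` for CSV exports).
#' @param columns Named character vector mapping canonical fields to
#'   file column names; defaults to identity.
#' @return A data.frame of class `ddg_records`.
#' @export
read_ddg_table <- function(file, sep = "\t",
                           columns = c(position = "position", wt_aa = "wt_aa",
                                       mut_aa = "mut_aa",
                                       ddG_F_monomer = "ddG_F_monomer",
                                       ddG_F_dimer = "ddG_F_dimer",
                                       ddG_B = "ddG_B")) {
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("position", "wt_aa", "mut_aa", "ddG_F_monomer", "ddG_F_dimer")
  miss <- setdiff(need, names(columns))
  if (length(miss)) stop("column mapping lacks: ", paste(miss, collapse = ", "))
  get <- function(field) {
    cn <- columns[[field]]
    if (is.null(cn) || !cn %in% names(raw)) {
      if (field == "ddG_B") return(rep(NA_real_, nrow(raw)))
      stop("input lacks column ", sQuote(cn), " for field ", field)
    }
    raw[[cn]]
  }
  ddg_records(data.frame(position = as.integer(get("position")),
                         wt_aa = toupper(get("wt_aa")),
                         mut_aa = toupper(get("mut_aa")),
                         ddG_F_monomer = as.numeric(get("ddG_F_monomer")),
                         ddG_F_dimer = as.numeric(get("ddG_F_dimer")),
                         ddG_B = as.numeric(get("ddG_B")),
                         stringsAsFactors = FALSE))
}

#' Validate and class a ddG record table
#' @param records data.frame with columns position, wt_aa, mut_aa,
#'   ddG_F_monomer, ddG_F_dimer, ddG_B.
#' @return The validated data.frame, classed `ddg_records`.
#' @export
ddg_records <- function(records) {
  if (any(records$wt_aa == records$mut_aa))
    stop("records with wt_aa == mut_aa are not mutations")
  num <- c("ddG_F_monomer", "ddG_F_dimer")
  for (cn in num)
    if (!all(is.finite(records[[cn]]))) stop("non-finite values in ", cn)
  class(records) <- unique(c("ddg_records", class(records)))
  records
}

#' Screening criteria for dimer-destabilizing interface mutations
#'
#' @param interface_positions Residue positions at the dimer interface
#'   (e.g. from [interface_residues()]).
#' @param ddgf_gap_min Minimum ddG_F(dimer) - ddG_F(monomer) gap
#'   (kcal/mol): the mutation must destabilize the dimer fold distinctly
#'   more than the monomer fold.
#' @param ddgb_min Minimum predicted binding-affinity penalty ddG_B
#'   (kcal/mol).
#' @param excluded_mutant_aas Replacement residues excluded outright
#'   (defaults G, P, C: secondary-structure breakers and disulfide
#'   formers).
#' @param require_charge_preserving Reject mutations that change the
#'   formal charge at pH 7.
#' @return A `screen_criteria` list.
#' @export
screen_criteria <- function(interface_positions, ddgf_gap_min = 2,
                            ddgb_min = 4,
                            excluded_mutant_aas = c("G", "P", "C"),
                            require_charge_preserving = TRUE) {
  stopifnot(ddgf_gap_min >= 0, ddgb_min >= 0)
  structure(list(interface_positions = sort(unique(as.integer(interface_positions))),
                 ddgf_gap_min = ddgf_gap_min, ddgb_min = ddgb_min,
                 excluded_mutant_aas = toupper(excluded_mutant_aas),
                 require_charge_preserving = isTRUE(require_charge_preserving)),
            class = "screen_criteria")
}

#' Formal charge change of a point mutation at pH 7
#'
#' Asp/Glu carry -1, Lys/Arg +1, histidine is treated as neutral.
#'
#' @param wt_aa,mut_aa One-letter amino-acid codes (vectorised).
#' @return Integer charge delta, q(mut) - q(wt).
#' @export
charge_delta <- function(wt_aa, mut_aa) {
  q <- function(aa) {
    aa <- toupper(aa)
    bad <- !(aa %in% names(.AA_CHARGE))
    if (any(bad)) stop("unknown amino-acid code: ",
                       paste(unique(aa[bad]), collapse = ", "))
    unname(.AA_CHARGE[aa])
  }
  as.integer(q(mut_aa) - q(wt_aa))
}

#' Screen candidate mutations for selective dimer destabilization
#'
#' Applies the prioritization ledger for dimer-interface mutations, in
#' order: interface membership, folding-energy gap
#' (ddG_F dimer - monomer >= `ddgf_gap_min`), excluded replacement
#' residues, charge preservation, and binding penalty
#' (ddG_B >= `ddgb_min`). Every record is annotated with the first
#' filter it fails; survivors are ranked by ddG_B descending.
#'
#' @param records A `ddg_records` table.
#' @param criteria A `screen_criteria` object.
#' @return A `screen_result`: `ledger` (all records with `fail_reason`,
#'   `""` for survivors) and `survivors` (ranked subset).
#' @export
screen_destabilizing <- function(records, criteria) {
  if (!nrow(records)) {
    ledger <- cbind(records, fail_reason = character(0))
    return(structure(list(ledger = ledger, survivors = ledger),
                     class = "screen_result"))
  }
  known <- criteria$interface_positions %in% records$position
  if (!all(known))
    warning("criteria reference position(s) absent from records: ",
            paste(criteria$interface_positions[!known], collapse = ", "))
  r <- records
  fail <- character(nrow(r))
  gap <- r$ddG_F_dimer - r$ddG_F_monomer
  chg <- charge_delta(r$wt_aa, r$mut_aa)
  tests <- list(
    not_interface = !(r$position %in% criteria$interface_positions),
    ddgf_gap = gap < criteria$ddgf_gap_min,
    excluded_aa = r$mut_aa %in% criteria$excluded_mutant_aas,
    charge_change = criteria$require_charge_preserving & chg != 0L,
    ddgb = is.na(r$ddG_B) | r$ddG_B < criteria$ddgb_min
  )
  for (nm in names(tests)) {
    hit <- fail == "" & tests[[nm]]
    fail[hit] <- nm
  }
  ledger <- r
  ledger$ddgf_gap <- gap
  ledger$charge_delta <- chg
  ledger$fail_reason <- fail
  surv <- ledger[fail == "", , drop = FALSE]
  surv <- surv[order(-surv$ddG_B, surv$position, surv$mut_aa), , drop = FALSE]
  rownames(surv) <- NULL
  structure(list(ledger = ledger, survivors = surv), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("mutation screen:", nrow(x$ledger), "candidate(s),",
      nrow(x$survivors), "survivor(s)\n")
  if (nrow(x$survivors)) {
    top <- utils::head(x$survivors, 10)
    cat(sprintf("  %s%d%s  ddG_B %.2f kcal/mol\n", top$wt_aa, top$position,
                top$mut_aa, top$ddG_B), sep = "")
  }
  invisible(x)
}
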
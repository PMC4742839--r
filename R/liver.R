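#' Liver-specific model modifications
#'
#' Adds the three reactions a hepatocyte model needs on top of a generic
#' human reconstruction: a biomass reaction, a glycogen demand (sink) and an
#' apo-glycogenin demand. Glycogenin is the protein primer on which glycogen
#' is built, so letting the model drain both species permits net glycogen
#' synthesis and degradation at steady state. If the glycogen or
#' apo-glycogenin species are absent they are created (a message notes this).
#'
#' The stoichiometry of the biomass reaction is a configurable placeholder
#' draining one unit of each designated precursor.
#'
#' @param model a `metabolic_model`.
#' @param glycogen_id,apo_glycogenin_id metabolite ids of glycogen and
#'   apo-glycogenin.
#' @param biomass_precursors metabolite ids drained (one unit each) by the
#'   biomass reaction; defaults to the glycogen species.
#' @param compartment compartment used when the species must be created.
#' @return A copy of the model with exactly three added reactions
#'   (`biomass_liver`, `DM_<glycogen>`, `DM_<apo-glycogenin>`), all
#'   irreversible.
#' @export
add_liver_modifications <- function(model,
                                    glycogen_id = "glycogen_c",
                                    apo_glycogenin_id = "apo_glycogenin_c",
                                    biomass_precursors = glycogen_id,
                                    compartment = "c") {
  new_ids <- c("biomass_liver",
               paste0("DM_", glycogen_id),
               paste0("DM_", apo_glycogenin_id))
  clash <- intersect(new_ids, model$reactions$id)
  if (length(clash) > 0) {
    stop("liver modification reaction id(s) already present: ",
         paste(clash, collapse = ", "))
  }

  mets <- model$metabolites
  for (mid in unique(c(glycogen_id, apo_glycogenin_id))) {
    if (!(mid %in% mets$id)) {
      message("adding missing species ", mid, " to the model")
      mets <- rbind(mets, data.frame(id = mid, name = mid,
                                     compartment = compartment,
                                     stringsAsFactors = FALSE))
    }
  }
  missing_prec <- setdiff(biomass_precursors, mets$id)
  if (length(missing_prec) > 0) {
    stop("biomass precursors not in the model: ",
         paste(missing_prec, collapse = ", "))
  }

  add <- data.frame(
    id = new_ids,
    lower_bound = c(0, 0, 0),
    upper_bound = c(1000, 1000, 1000),
    pathway = "liver_modifications",
    gpr = "",
    stringsAsFactors = FALSE
  )
  stoich_add <- list(
    stats::setNames(rep(-1, length(biomass_precursors)), biomass_precursors),
    stats::setNames(-1, glycogen_id),
    stats::setNames(-1, apo_glycogenin_id)
  )
  names(stoich_add) <- new_ids

  rxns <- model$reactions[, c("id", "lower_bound", "upper_bound",
                              "pathway", "gpr")]
  metabolic_model(mets, rbind(rxns, add),
                  c(model$stoichiometry, stoich_add),
                  genes = model$genes)
}
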
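#' Read and write metabolic models
#'
#' Models are exchanged either as SBML (Level 3 + fbc is emitted; Level 2
#' with kinetic-law bounds and `GENE_ASSOCIATION` notes, the dialect of the
#' classic Recon 1 distribution, is also read) or as a JSON dialect mirroring
#' the package's in-memory structure: top-level `metabolites`, `reactions`
#' (each carrying `stoichiometry` as a metabolite-to-coefficient map,
#' `lower_bound`, `upper_bound`, `pathway`, `gpr`) and `genes`.
#'
#' @param path file path.
#' @param format `"sbml"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @return [load_model()] returns a `metabolic_model`; the writers return
#'   `path` invisibly.
#' @export
load_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else {
      "json"
    }
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         sbml = read_sbml_model(path),
         json = read_json_model(path))
}

# ---------------------------------------------------------------- JSON ----

read_json_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$metabolites) || is.null(obj$reactions)) {
    stop("JSON model must contain 'metabolites' and 'reactions': ", path)
  }
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(obj$reactions, function(r) {
    data.frame(id = r$id,
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               pathway = r$pathway %||% NA_character_,
               gpr = r$gpr %||% "",
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(obj$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    if (is.null(st)) stop("reaction ", r$id, " has no stoichiometry")
    st
  })
  names(stoich) <- rxns$id
  genes <- if (is.null(obj$genes)) NULL else as.character(unlist(obj$genes))
  metabolic_model(mets, rxns, stoich, genes = genes)
}

#' @rdname load_model
#' @param model a `metabolic_model`.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    list(id = r$id,
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         pathway = if (is.na(r$pathway)) NULL else r$pathway,
         gpr = r$gpr,
         stoichiometry = as.list(model$stoichiometry[[j]]))
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  obj <- list(metabolites = mets, reactions = rxns,
              genes = as.list(model$genes))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# ---------------------------------------------------------------- SBML ----

# attribute lookup tolerant of namespace prefixes ("fbc:foo" vs "foo")
xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(name, sub("^[^:]+:", "", names(at)))
  if (is.na(hit)) NA_character_ else unname(at[hit])
}

xfind <- function(node, localname) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", localname))
}

# fbc geneProductAssociation subtree -> GPR string
fbc_assoc_to_gpr <- function(node, gp_labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xattr(node, "geneProduct")
    lbl <- gp_labels[[ref]]
    return(if (is.null(lbl) || is.na(lbl)) ref else lbl)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_assoc_to_gpr, character(1),
                  gp_labels = gp_labels)
  if (nm == "and") {
    paste0("(", paste(parts, collapse = " and "), ")")
  } else if (nm == "or") {
    paste0("(", paste(parts, collapse = " or "), ")")
  } else if (length(parts) == 1) {
    parts
  } else {
    stop("unsupported gene association element: ", nm)
  }
}

# notes fields of the classic COBRA SBML dialect: "GENE_ASSOCIATION: ..."
notes_field <- function(node, field) {
  notes <- xfind(node, "notes")
  if (length(notes) == 0) return(NA_character_)
  txt <- xml2::xml_text(xml2::xml_find_all(
    notes[[1]], ".//*[local-name()='p' or local-name()='html:p']"))
  if (length(txt) == 0) txt <- xml2::xml_text(notes[[1]])
  pat <- paste0("^\\s*", field, "\\s*:\\s*(.*)$")
  hits <- regmatches(txt, regexec(pat, txt))
  for (h in hits) if (length(h) == 2) return(trimws(h[2]))
  NA_character_
}

read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e)))
  model_node <- xfind(doc, "model")
  if (length(model_node) == 0) stop("no <model> element in ", path)
  model_node <- model_node[[1]]

  sp_nodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0) stop("no species declared in ", path)
  mets <- data.frame(
    id = vapply(sp_nodes, xattr, character(1), name = "id"),
    name = vapply(sp_nodes, function(n) {
      v <- xattr(n, "name"); if (is.na(v)) xattr(n, "id") else v
    }, character(1)),
    compartment = vapply(sp_nodes, function(n) {
      v <- xattr(n, "compartment"); if (is.na(v)) "c" else v
    }, character(1)),
    boundary = vapply(sp_nodes, function(n) {
      identical(xattr(n, "boundaryCondition"), "true")
    }, logical(1)),
    stringsAsFactors = FALSE
  )

  # fbc flux-bound parameters
  par_nodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_vals <- stats::setNames(
    vapply(par_nodes, function(n) as.numeric(xattr(n, "value")), numeric(1)),
    vapply(par_nodes, xattr, character(1), name = "id"))

  # fbc gene products (id -> label)
  gp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='geneProduct']")
  gp_labels <- stats::setNames(
    vapply(gp_nodes, function(n) {
      v <- xattr(n, "label"); if (is.na(v)) xattr(n, "id") else v
    }, character(1)),
    vapply(gp_nodes, xattr, character(1), name = "id"))

  rxn_nodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxn_nodes) == 0) stop("no reactions declared in ", path)

  n_bad_gpr <- 0L
  rows <- vector("list", length(rxn_nodes))
  stoich <- vector("list", length(rxn_nodes))
  boundary_ids <- mets$id[mets$boundary]
  for (k in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[k]]
    rid <- xattr(rn, "id")
    reversible <- !identical(xattr(rn, "reversible"), "false")

    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(
        rn, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']",
                    side))
      for (ref in refs) {
        sid <- xattr(ref, "species")
        coef <- suppressWarnings(as.numeric(xattr(ref, "stoichiometry")))
        if (is.na(coef)) coef <- 1
        st[sid] <- (if (sid %in% names(st)) st[[sid]] else 0) + sign * coef
      }
    }
    # boundary species act as the implicit "outside" of exchange reactions
    st <- st[!(names(st) %in% boundary_ids)]
    if (length(st) == 0) {
      stop("reaction ", rid, " has no non-boundary species in ", path)
    }

    # bounds: fbc attributes, then kinetic-law parameters, then reversibility
    lb <- ub <- NA_real_
    lb_ref <- xattr(rn, "lowerFluxBound")
    ub_ref <- xattr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_vals)) lb <- par_vals[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_vals)) ub <- par_vals[[ub_ref]]
    if (is.na(lb) || is.na(ub)) {
      kl_par <- xml2::xml_find_all(
        rn, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      for (p in kl_par) {
        pid <- xattr(p, "id")
        pv <- suppressWarnings(as.numeric(xattr(p, "value")))
        if (identical(pid, "LOWER_BOUND") && is.na(lb)) lb <- pv
        if (identical(pid, "UPPER_BOUND") && is.na(ub)) ub <- pv
      }
    }
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000

    # GPR: fbc geneProductAssociation, else GENE_ASSOCIATION note
    gpr <- ""
    assoc <- xfind(rn, "geneProductAssociation")
    if (length(assoc) > 0) {
      kids <- xml2::xml_children(assoc[[1]])
      if (length(kids) > 0) {
        gpr <- tryCatch(fbc_assoc_to_gpr(kids[[1]], as.list(gp_labels)),
                        error = function(e) NA_character_)
      }
    } else {
      note_gpr <- notes_field(rn, "GENE_ASSOCIATION")
      if (!is.na(note_gpr) && nzchar(note_gpr)) gpr <- note_gpr
    }
    if (is.na(gpr)) {
      gpr <- ""
      n_bad_gpr <- n_bad_gpr + 1L
    } else if (nzchar(gpr)) {
      ok <- tryCatch({ parse_gpr(gpr); TRUE }, error = function(e) FALSE)
      if (!ok) {
        gpr <- ""
        n_bad_gpr <- n_bad_gpr + 1L
      }
    }

    pathway <- notes_field(rn, "SUBSYSTEM")
    rows[[k]] <- data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                            pathway = pathway, gpr = gpr,
                            stringsAsFactors = FALSE)
    stoich[[k]] <- st
  }
  rxns <- do.call(rbind, rows)
  names(stoich) <- rxns$id
  if (n_bad_gpr > 0) {
    warning(n_bad_gpr, " unreadable GPR rule(s) treated as empty")
  }
  # boundary species are the implicit exterior, not model metabolites
  metabolic_model(mets[!mets$boundary, c("id", "name", "compartment")],
                  rxns, stoich)
}

#' @rdname load_model
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

  gpr_to_fbc <- function(tree) {
    if (is.null(tree)) return("")
    if (tree$op == "gene") {
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     sanitize(tree$id)))
    }
    inner <- paste(vapply(tree$args, gpr_to_fbc, character(1)),
                   collapse = "")
    sprintf("<fbc:%s>%s</fbc:%s>", tree$op, inner, tree$op)
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '<model id="model" fbc:strict="true">')

  comps <- unique(model$metabolites$compartment)
  lines <- c(lines, "<listOfCompartments>",
             sprintf('<compartment id="%s" constant="true"/>', esc(comps)),
             "</listOfCompartments>")

  lines <- c(lines, "<listOfSpecies>",
             sprintf(paste0('<species id="%s" name="%s" compartment="%s" ',
                            'hasOnlySubstanceUnits="false" ',
                            'boundaryCondition="false" constant="false"/>'),
                     esc(model$metabolites$id), esc(model$metabolites$name),
                     esc(model$metabolites$compartment)),
             "</listOfSpecies>")

  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  par_ids_lb <- sprintf("lb_%d", seq_along(lb))
  par_ids_ub <- sprintf("ub_%d", seq_along(ub))
  lines <- c(lines, "<listOfParameters>",
             sprintf('<parameter id="%s" value="%.17g" constant="true"/>',
                     c(par_ids_lb, par_ids_ub), c(lb, ub)),
             "</listOfParameters>")

  all_genes <- model$genes
  if (length(all_genes) > 0) {
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               sprintf('<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                       sanitize(all_genes), esc(all_genes)),
               "</fbc:listOfGeneProducts>")
  }

  lines <- c(lines, "<listOfReactions>")
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    st <- model$stoichiometry[[j]]
    open <- sprintf(paste0('<reaction id="%s" reversible="%s" fast="false" ',
                           'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
                    esc(r$id), if (lb[j] < 0) "true" else "false",
                    par_ids_lb[j], par_ids_ub[j])
    body <- character(0)
    if (!is.na(r$pathway)) {
      body <- c(body,
                "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
                sprintf("<p>SUBSYSTEM: %s</p>", esc(r$pathway)),
                "</body></notes>")
    }
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      body <- c(body, "<listOfReactants>",
                sprintf(paste0('<speciesReference species="%s" ',
                               'stoichiometry="%.17g" constant="true"/>'),
                        esc(names(reac)), -unname(reac)),
                "</listOfReactants>")
    }
    if (length(prod)) {
      body <- c(body, "<listOfProducts>",
                sprintf(paste0('<speciesReference species="%s" ',
                               'stoichiometry="%.17g" constant="true"/>'),
                        esc(names(prod)), unname(prod)),
                "</listOfProducts>")
    }
    tree <- parse_gpr(r$gpr)
    if (!is.null(tree)) {
      body <- c(body, "<fbc:geneProductAssociation>", gpr_to_fbc(tree),
                "</fbc:geneProductAssociation>")
    }
    lines <- c(lines, open, body, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Structural counts of a model
#'
#' Convenience summary used to sanity-check a freshly parsed reconstruction:
#' metabolite count, total reactions, internal (non-exchange/demand)
#' reactions, and gene count.
#'
#' @param model a `metabolic_model`.
#' @return Named numeric vector.
#' @export
model_summary_counts <- function(model) {
  c(metabolites = nrow(model$metabolites),
    reactions_total = nrow(model$reactions),
    reactions_internal = sum(!model$reactions$is_exchange),
    genes = length(model$genes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
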
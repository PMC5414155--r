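# Reading and writing networks: internal TSV reaction-table dialect and a
# COBRA-flavoured SBML Level 3 (+fbc) subset.

#' Load a metabolic network from disk
#'
#' @param path file path.
#' @param dialect "sbml" or "reaction-table" (TSV with columns id, equation,
#'   lb, ub, gpr; equations use "->" / "<=>" arrows). Guessed from the file
#'   extension when missing.
#' @param gam,ngam optional maintenance values to annotate (see
#'   [metabolicNetwork()] for how NGAM is imposed).
#' @return a validated [MetabolicNetwork-class] with exchange reactions
#'   auto-flagged.
#' @export
loadNetwork <- function(path, dialect = c("auto", "sbml", "reaction-table"),
                        gam = NA_real_, ngam = NA_real_) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "reaction-table"
  if (!file.exists(path)) stop("file not found: ", path)
  net <- switch(dialect,
                "sbml" = .readSBML(path),
                "reaction-table" = .readReactionTable(path))
  if (!is.na(gam)) net@gam <- gam
  if (!is.na(ngam)) {
    net@ngam <- ngam
    iatpm <- grep("ATPM", net@reactions$id)
    if (length(iatpm)) {
      net@reactions$lb[iatpm[1]] <- ngam
      net@reactions$ub[iatpm[1]] <- ngam
    }
  }
  validObject(net)
  net
}

#' Write a metabolic network to disk
#' @param network a MetabolicNetwork.
#' @param path output path.
#' @param dialect "sbml" or "reaction-table".
#' @export
writeNetwork <- function(network, path,
                         dialect = c("reaction-table", "sbml")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         "reaction-table" = .writeReactionTable(network, path),
         "sbml" = .writeSBML(network, path))
  invisible(path)
}

# ---- reaction-table dialect -------------------------------------------------

.parseEquation <- function(eq, rid) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<=>" else "->", fixed = TRUE)[[1]]
  if (length(sides) > 2 || !length(sides))
    stop("cannot parse equation for reaction '", rid, "': ", eq)
  parseSide <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, " + ", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9.]+) +(.*)$", tm))[[1]]
      if (length(m)) { coef <- as.numeric(m[2]); met <- m[3] }
      else { coef <- 1; met <- tm }
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- if (length(sides) == 2) parseSide(sides[2], +1) else numeric(0)
  sv <- lhs
  for (mt in names(rhs)) sv[mt] <- (if (mt %in% names(sv)) sv[[mt]] else 0) + rhs[[mt]]
  list(stoich = sv[sv != 0], reversible = rev)
}

.formatEquation <- function(sv, reversible) {
  fmtSide <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(v == 1, names(v), paste(.fmtNum(v), names(v))), collapse = " + ")
  }
  lhs <- -sv[sv < 0]; rhs <- sv[sv > 0]
  paste(fmtSide(lhs), if (reversible) "<=>" else "->", fmtSide(rhs))
}

.fmtNum <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
  out <- sub("(\\.[0-9]*?)0+$", "\\1", out)
  sub("\\.$", "", out)
}

.readReactionTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  need <- c("id", "equation", "lb", "ub")
  if (!all(need %in% names(tab)))
    stop("reaction table must have columns ", paste(need, collapse = ", "))
  stoich <- list()
  for (i in seq_len(nrow(tab))) {
    p <- .parseEquation(tab$equation[i], tab$id[i])
    stoich[[tab$id[i]]] <- p$stoich
  }
  mets <- unique(unlist(lapply(stoich, names)))
  rxn <- data.frame(id = tab$id, lb = as.numeric(tab$lb),
                    ub = as.numeric(tab$ub),
                    gpr = if ("gpr" %in% names(tab))
                      ifelse(nzchar(tab$gpr), tab$gpr, NA_character_)
                    else NA_character_,
                    stringsAsFactors = FALSE)
  met <- data.frame(id = mets, stringsAsFactors = FALSE)
  if ("formula" %in% names(tab)) {} # formulas live in a side table, not here
  metabolicNetwork(met, rxn, stoich)
}

.writeReactionTable <- function(network, path) {
  rxn <- network@reactions
  rev <- isReversible(network)
  eqs <- vapply(rxn$id, function(id) {
    sv <- network@S[, id]; sv <- sv[sv != 0]
    .formatEquation(sv, rev[[id]])
  }, character(1))
  out <- data.frame(id = rxn$id, equation = eqs,
                    lb = .fmtNum(rxn$lb), ub = .fmtNum(rxn$ub),
                    gpr = ifelse(is.na(rxn$gpr), "", rxn$gpr))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- SBML (Level 3 + fbc, COBRA flavour) ------------------------------------

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sbmlSanitize <- function(ids, prefix) {
  s <- gsub("(", "_op_", ids, fixed = TRUE)
  s <- gsub(")", "_cl_", s, fixed = TRUE)
  s <- gsub("[^A-Za-z0-9_]", "_", s)
  paste0(prefix, s)
}

.sbmlUnsanitize <- function(ids, prefix) {
  s <- sub(paste0("^", prefix), "", ids)
  s <- gsub("_op_", "(", s, fixed = TRUE)
  gsub("_cl_", ")", s, fixed = TRUE)
}

.writeSBML <- function(network, path) {
  met <- network@metabolites; rxn <- network@reactions
  mids <- .sbmlSanitize(met$id, "M_")
  rids <- .sbmlSanitize(rxn$id, "R_")
  comps <- unique(met$compartment)
  bounds <- sort(unique(c(rxn$lb, rxn$ub)))
  bid <- function(v) paste0("bnd_", match(v, bounds))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  ln <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
          sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
                  .SBML_NS, .FBC_NS),
          '<model id="model" fbc:strict="true">',
          "<listOfCompartments>",
          sprintf('<compartment id="%s" constant="true"/>', comps),
          "</listOfCompartments>",
          "<listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    attrs <- sprintf('id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
                     mids[i], esc(met$name[i]), met$compartment[i])
    if (!is.na(met$formula[i]))
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', met$formula[i]))
    if (!is.na(met$charge[i]))
      attrs <- paste0(attrs, sprintf(' fbc:charge="%d"', met$charge[i]))
    ln <- c(ln, sprintf("<species %s/>", attrs))
  }
  ln <- c(ln, "</listOfSpecies>", "<listOfParameters>",
          sprintf('<parameter id="%s" value="%s" constant="true"/>',
                  bid(bounds), .fmtNum(bounds)),
          "</listOfParameters>", "<listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    sv <- network@S[, j]; sv <- sv[sv != 0]
    smids <- .sbmlSanitize(names(sv), "M_")
    ln <- c(ln, sprintf('<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
                        rids[j], tolower(rxn$lb[j] < 0 && rxn$ub[j] > 0),
                        bid(rxn$lb[j]), bid(rxn$ub[j])))
    if (!is.na(rxn$gpr[j]))
      ln <- c(ln, "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
              sprintf("<p>GENE_ASSOCIATION: %s</p>", esc(rxn$gpr[j])),
              "</body></notes>")
    if (any(sv < 0)) {
      ln <- c(ln, "<listOfReactants>",
              sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                      smids[sv < 0], .fmtNum(-sv[sv < 0])),
              "</listOfReactants>")
    }
    if (any(sv > 0)) {
      ln <- c(ln, "<listOfProducts>",
              sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                      smids[sv > 0], .fmtNum(sv[sv > 0])),
              "</listOfProducts>")
    }
    ln <- c(ln, "</reaction>")
  }
  ln <- c(ln, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(ln, path)
}

.readSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure: ", conditionMessage(e)))
  ns <- c(s = .SBML_NS, fbc = .FBC_NS)
  nsAll <- tryCatch(xml2::xml_ns(doc), error = function(e) NULL)
  # tolerate other SBML levels by matching on local names
  species <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  if (!length(species)) stop("SBML format error: no species elements")
  getAttr <- function(nodes, name, fbcName = NULL) {
    v <- xml2::xml_attr(nodes, name)
    if (!is.null(fbcName)) {
      v2 <- xml2::xml_attr(nodes, fbcName)
      v <- ifelse(is.na(v), v2, v)
    }
    v
  }
  mid_raw <- getAttr(species, "id")
  met <- data.frame(id = .sbmlUnsanitize(mid_raw, "M_"),
                    name = getAttr(species, "name"),
                    compartment = getAttr(species, "compartment"),
                    formula = getAttr(species, "chemicalFormula", "fbc:chemicalFormula"),
                    charge = suppressWarnings(
                      as.integer(getAttr(species, "charge", "fbc:charge"))),
                    stringsAsFactors = FALSE)
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]
  met$compartment[is.na(met$compartment) | !nzchar(met$compartment)] <- "c"

  params <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rnodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  if (!length(rnodes)) stop("SBML format error: no reaction elements")
  stoich <- list(); rows <- list()
  for (rn in rnodes) {
    rid_raw <- xml2::xml_attr(rn, "id")
    rid <- .sbmlUnsanitize(rid_raw, "R_")
    sv <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rn, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (ref in refs) {
        sp_raw <- xml2::xml_attr(ref, "species")
        i <- match(sp_raw, mid_raw)
        if (is.na(i))
          stop("SBML validation error: reaction '", rid,
               "' references unknown species '", sp_raw, "'")
        sp <- met$id[i]
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        sv[sp] <- (if (sp %in% names(sv)) sv[[sp]] else 0) + sgn * st
      }
    }
    if (!length(sv))
      stop("SBML validation error: reaction '", rid, "' has no participants")
    lbRef <- xml2::xml_attr(rn, "lowerFluxBound")
    ubRef <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbRef) && lbRef %in% names(pval)) pval[[lbRef]] else NA
    ub <- if (!is.na(ubRef) && ubRef %in% names(pval)) pval[[ubRef]] else NA
    if (is.na(lb) || is.na(ub)) {
      # legacy COBRA: kineticLaw parameters LOWER_BOUND / UPPER_BOUND
      kl <- xml2::xml_find_all(rn, ".//*[local-name()='parameter']")
      kid <- xml2::xml_attr(kl, "id")
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lb)) lb <- if ("LOWER_BOUND" %in% kid) kv[match("LOWER_BOUND", kid)] else NA
      if (is.na(ub)) ub <- if ("UPPER_BOUND" %in% kid) kv[match("UPPER_BOUND", kid)] else NA
    }
    revAttr <- xml2::xml_attr(rn, "reversible")
    if (is.na(lb)) lb <- if (identical(revAttr, "false")) 0 else -.LP_BIG
    if (is.na(ub)) ub <- .LP_BIG
    gpr <- NA_character_
    notes <- xml2::xml_find_first(rn, ".//*[local-name()='p'][contains(text(), 'GENE_ASSOCIATION')]")
    if (!inherits(notes, "xml_missing")) {
      gpr <- trimws(sub("^\\s*GENE_ASSOCIATION:\\s*", "", xml2::xml_text(notes)))
      if (!nzchar(gpr)) gpr <- NA_character_
    } else {
      gpa <- xml2::xml_find_all(rn, ".//*[local-name()='geneProductRef']")
      if (length(gpa)) {
        gids <- xml2::xml_attr(gpa, "geneProduct")
        gpr <- paste(unique(sub("^G_", "", gids)), collapse = " or ")
      }
    }
    stoich[[rid]] <- sv
    rows[[rid]] <- data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                              stringsAsFactors = FALSE)
  }
  rxn <- do.call(rbind, rows)
  metabolicNetwork(met, rxn, stoich)
}

#' Gene ids referenced by the network's GPR strings
#' @param network a MetabolicNetwork
#' @return character vector of unique gene identifiers.
#' @export
geneIds <- function(network) {
  gpr <- network@reactions$gpr
  gpr <- gpr[!is.na(gpr)]
  toks <- unlist(strsplit(gpr, "[()\\s]+", perl = TRUE))
  sort(unique(toks[nzchar(toks) & !(tolower(toks) %in% c("and", "or"))]))
}

#' Reactions affected by knocking out a gene
#'
#' Maps a gene to the reactions whose GPR mentions it and whose boolean GPR
#' evaluates to FALSE when the gene is removed.
#' @param network a MetabolicNetwork
#' @param genes character vector of gene ids to delete.
#' @return character vector of disabled reaction ids.
#' @export
reactionsDisabledBy <- function(network, genes) {
  rxn <- network@reactions
  out <- character(0)
  for (i in seq_len(nrow(rxn))) {
    g <- rxn$gpr[i]
    if (is.na(g)) next
    expr <- gsub("\\bAND\\b", "&&", gsub("\\bOR\\b", "||", g, ignore.case = TRUE),
                 ignore.case = TRUE)
    toks <- unique(unlist(strsplit(g, "[()\\s]+", perl = TRUE)))
    toks <- toks[nzchar(toks) & !(tolower(toks) %in% c("and", "or"))]
    env <- new.env()
    for (tk in toks) assign(tk, !(tk %in% genes), envir = env)
    expr <- gsub("([A-Za-z_][A-Za-z0-9_.]*)",
                 "`\\1`", expr)
    expr <- gsub("`&&`", "&&", gsub("`\\|\\|`", "||", expr))
    val <- tryCatch(eval(parse(text = expr), envir = env), error = function(e) NA)
    if (identical(val, FALSE)) out <- c(out, rxn$id[i])
  }
  out
}
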
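## Reduced core cancer metabolic network and its JSON/SBML I/O.
##
## Single-compartment reconstruction (~66 reactions) covering glucose uptake,
## upper and lower glycolysis, lactate exchange, pyruvate entry into a lumped
## TCA cycle, glutaminolysis with glutamate -> alpha-ketoglutarate entry,
## oxidative phosphorylation with an O2 exchange, an ATP demand, hyaluronic
## acid (HA) synthesis from UDP-glucuronate + UDP-N-acetylglucosamine, a
## biomass (growth) drain, and exchange reactions for all 20 canonical amino
## acids. Currency bookkeeping is simplified: FADH2 is folded into NADH,
## UTP into ATP, and water/protons/phosphate are not tracked.

AMINO_ACIDS <- c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
                 "glutamate", "glutamine", "glycine", "histidine", "isoleucine",
                 "leucine", "lysine", "methionine", "phenylalanine", "proline",
                 "serine", "threonine", "tryptophan", "tyrosine", "valine")

## amino acids whose exchange constraints are omitted for LP convergence
OMITTED_AMINO_ACIDS <- c("glycine", "leucine", "lysine", "phenylalanine",
                         "threonine", "tryptophan", "tyrosine", "valine")

#' Canonical amino acids and the default omitted set
#'
#' `amino_acid_names()` returns the 20 canonical amino acid names used
#' throughout the package; `omitted_amino_acids()` the eight whose exchange
#' fluxes are left unconstrained when building FBA constraint sets (their
#' measured bounds tend to make the LP infeasible).
#' @return character vector of metabolite names.
#' @export
amino_acid_names <- function() AMINO_ACIDS

#' @rdname amino_acid_names
#' @export
omitted_amino_acids <- function() OMITTED_AMINO_ACIDS

aa_met <- function(aa) {
  map <- c(alanine = "ala", arginine = "arg", asparagine = "asn",
           aspartate = "asp", cysteine = "cys", glutamate = "glu",
           glutamine = "gln", glycine = "gly", histidine = "his",
           isoleucine = "ile", leucine = "leu", lysine = "lys",
           methionine = "met", phenylalanine = "phe", proline = "pro",
           serine = "ser", threonine = "thr", tryptophan = "trp",
           tyrosine = "tyr", valine = "val")
  unname(map[aa])
}

#' Reduced core cancer metabolic network
#'
#' Builds the packaged reduced network used for the HA-maximization flux
#' balance analysis. Flux units are mmol/gDW/h except the growth reaction
#' (1/h). Exchange reactions carry a single metabolite with coefficient -1,
#' so positive exchange flux means secretion and negative flux uptake.
#'
#' Tagged reactions: `ha_synthesis` (HAS), `atp_demand` (ATPM), `growth`
#' (GROWTH), `o2_exchange` (EX_o2), plus the bioenergetic comparison subset
#' `upper_glycolysis` (PFK), `pyr_to_lac` (LDH), `glu_to_akg` (GDH) and
#' `akg_to_succoa` (AKGDH).
#'
#' @return a `metabolic_network` object; see [load_network()] for the fields.
#' @examples
#' net <- toy_core_network()
#' net
#' @export
toy_core_network <- function() {
  rx <- list()
  add <- function(id, stoich, lb = 0, ub = 1000, tags = character()) {
    rx[[id]] <<- list(id = id, stoich = stoich, lb = lb, ub = ub, tags = tags)
  }
  ex_map <- c()
  add_ex <- function(metabolite, met_id, lb = -1000, ub = 1000,
                     tags = character()) {
    id <- paste0("EX_", met_id)
    add(id, stats::setNames(-1, met_id), lb, ub, tags)
    ex_map[[metabolite]] <<- id
  }

  ## exchanges
  add_ex("glucose", "glc")
  add_ex("lactate", "lac")
  add_ex("oxygen", "o2", lb = -1000, ub = 0, tags = "o2_exchange")
  add_ex("co2", "co2", lb = 0)
  add_ex("ammonium", "nh4")
  add_ex("hyaluronan", "ha", lb = 0)
  for (aa in AMINO_ACIDS) add_ex(aa, aa_met(aa))

  rev <- -1000
  ## glycolysis
  add("HEX1", c(glc = -1, atp = -1, g6p = 1, adp = 1))
  add("PGI",  c(g6p = -1, f6p = 1), lb = rev)
  add("PFK",  c(f6p = -1, atp = -1, fbp = 1, adp = 1), tags = "upper_glycolysis")
  add("FBA",  c(fbp = -1, g3p = 2), lb = rev)
  add("GAPD", c(g3p = -1, nad = -1, adp = -1, pep = 1, nadh = 1, atp = 1),
      lb = rev)
  add("PYK",  c(pep = -1, adp = -1, pyr = 1, atp = 1))
  add("LDH",  c(pyr = -1, nadh = -1, lac = 1, nad = 1), lb = rev,
      tags = "pyr_to_lac")
  ## TCA (lumped) and anaplerosis
  add("PDH",  c(pyr = -1, nad = -1, accoa = 1, nadh = 1, co2 = 1))
  add("CS",   c(accoa = -1, oaa = -1, cit = 1))
  add("IDH",  c(cit = -1, nad = -1, akg = 1, nadh = 1, co2 = 1))
  add("AKGDH", c(akg = -1, nad = -1, succoa = 1, nadh = 1, co2 = 1),
      tags = "akg_to_succoa")
  add("SUCOAS", c(succoa = -1, adp = -1, nad = -2, oaa = 1, atp = 1, nadh = 2))
  add("PC",   c(pyr = -1, atp = -1, co2 = -1, oaa = 1, adp = 1))
  add("PEPCK", c(oaa = -1, atp = -1, pep = 1, co2 = 1, adp = 1))
  ## respiration and ATP demand
  add("OXPHOS", c(nadh = -1, o2 = -0.5, adp = -2.5, nad = 1, atp = 2.5))
  add("ATPM", c(atp = -1, adp = 1), lb = 1, tags = "atp_demand")
  ## glutaminolysis and amino acid metabolism
  add("GLS",  c(gln = -1, glu = 1, nh4 = 1))
  add("GS",   c(glu = -1, nh4 = -1, atp = -1, gln = 1, adp = 1))
  add("GDH",  c(glu = -1, nad = -1, akg = 1, nh4 = 1, nadh = 1), lb = rev,
      tags = "glu_to_akg")
  add("ALT",  c(pyr = -1, glu = -1, ala = 1, akg = 1), lb = rev)
  add("AST",  c(oaa = -1, glu = -1, asp = 1, akg = 1), lb = rev)
  add("ASNS", c(asp = -1, gln = -1, atp = -1, asn = 1, glu = 1, adp = 1))
  add("ASNASE", c(asn = -1, asp = 1, nh4 = 1))
  add("SERSYN", c(g3p = -1, glu = -1, nad = -1, ser = 1, akg = 1, nadh = 1))
  add("SERDEG", c(ser = -1, pyr = 1, nh4 = 1))
  add("SHMT", c(ser = -1, gly = 1, c1 = 1), lb = rev)
  add("C1OX", c(c1 = -1, nad = -1, co2 = 1, nadh = 1))
  add("PROSYN", c(glu = -1, atp = -1, nadh = -2, pro = 1, adp = 1, nad = 2))
  add("PRODEG", c(pro = -1, nad = -2, glu = 1, nadh = 2))
  ## catabolism of essential amino acids with constrained exchanges
  add("ARGDEG", c(arg = -1, glu = 1, nh4 = 2, co2 = 1))
  add("CYSDEG", c(cys = -1, pyr = 1, nh4 = 1))
  add("HISDEG", c(his = -1, glu = 1, c1 = 1, nh4 = 1))
  add("ILEDEG", c(ile = -1, nad = -2, accoa = 1, succoa = 1, nh4 = 1, nadh = 2))
  add("METDEG", c(met = -1, nad = -1, atp = -1, succoa = 1, nh4 = 1, c1 = 1,
                  nadh = 1, adp = 1))
  ## hyaluronic acid synthesis (one disaccharide unit)
  add("UDPGLCUA", c(g6p = -1, atp = -1, nad = -2, udpglcua = 1, adp = 1,
                    nadh = 2))
  add("UDPGLCNAC", c(f6p = -1, gln = -1, accoa = -1, atp = -1, udpglcnac = 1,
                     glu = 1, adp = 1))
  add("HAS", c(udpglcua = -1, udpglcnac = -1, ha = 1), tags = "ha_synthesis")
  ## biomass drain: 0.25 mmol/gDW of each amino acid, 30 mmol ATP (GAM),
  ## plus carbohydrate and lipid precursor pulls
  bio <- stats::setNames(rep(-0.25, 20), aa_met(AMINO_ACIDS))
  bio <- c(bio, atp = -30, adp = 30, g6p = -1, accoa = -0.5)
  add("GROWTH", bio, tags = "growth")

  network_from_reactions(rx, ex_map, id = "core_cancer_reduced")
}

## Assemble a metabolic_network from a named reaction list
network_from_reactions <- function(rx, exchange_map, id = "network") {
  mets <- sort(unique(unlist(lapply(rx, function(r) names(r$stoich)))))
  S <- matrix(0, length(mets), length(rx),
              dimnames = list(mets, names(rx)))
  for (r in rx) S[names(r$stoich), r$id] <- r$stoich
  net <- structure(list(
    id = id,
    metabolites = mets,
    reactions = names(rx),
    S = S,
    lb = vapply(rx, function(r) r$lb, numeric(1)),
    ub = vapply(rx, function(r) r$ub, numeric(1)),
    tags = lapply(rx, function(r) r$tags),
    exchange_map = unlist(exchange_map)
  ), class = "metabolic_network")
  validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks the structural invariants the FBA engine relies on: `lb <= ub`
#' everywhere, every exchange reaction touching exactly one metabolite, every
#' internal metabolite participating in at least two reactions, all tagged
#' roles (`ha_synthesis`, `atp_demand`, `growth`, `o2_exchange`) present, and
#' feasibility of the default bounds (the HA-maximization LP must be optimal
#' with a nonnegative objective).
#'
#' @param net a `metabolic_network`.
#' @param check_feasible also solve the default LP (default TRUE).
#' @return `net` invisibly; errors describe the first violated invariant.
#' @export
validate_network <- function(net, check_feasible = TRUE) {
  stopifnot(inherits(net, "metabolic_network"))
  if (any(net$lb > net$ub))
    stop("network invalid: lb > ub for ",
         paste(net$reactions[net$lb > net$ub], collapse = ", "))
  for (ex in net$exchange_map) {
    nz <- sum(net$S[, ex] != 0)
    if (nz != 1L)
      stop("exchange reaction ", ex, " touches ", nz, " metabolites (need 1)")
  }
  deg <- rowSums(net$S != 0)
  if (any(deg < 2))
    stop("unbalanced metabolites (single reaction): ",
         paste(net$metabolites[deg < 2], collapse = ", "))
  for (tag in c("ha_synthesis", "atp_demand", "growth", "o2_exchange")) {
    if (length(tagged_reaction(net, tag)) != 1L)
      stop("network is missing a unique reaction tagged '", tag, "'")
  }
  if (check_feasible) {
    sol <- solve_fba(net, parsimonious = FALSE)
    if (sol$status != "optimal")
      stop("network infeasible under default bounds (status ", sol$status, ")")
  }
  invisible(net)
}

#' Look up a reaction by tag
#' @param net a `metabolic_network`.
#' @param tag tag string, e.g. "ha_synthesis".
#' @return reaction id(s) carrying the tag (possibly empty).
#' @export
tagged_reaction <- function(net, tag) {
  net$reactions[vapply(net$tags, function(t) tag %in% t, logical(1))]
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network '", x$id, "': ", length(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions (",
      length(x$exchange_map), " exchanges)\n", sep = "")
  cat("Tagged:",
      paste(vapply(c("ha_synthesis", "atp_demand", "growth", "o2_exchange"),
                   function(t) paste0(t, "=", tagged_reaction(x, t)[1]),
                   character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a metabolic network as JSON
#'
#' The JSON schema mirrors the in-memory object: `metabolites[]` and
#' `reactions[]` with `{id, stoich{met: coef}, lb, ub, tags[]}` plus an
#' `exchange_map` of metabolite name to exchange reaction id.
#'
#' @param path file path.
#' @return `load_network()` returns a validated `metabolic_network`;
#'   `write_network()` returns `path` invisibly.
#' @export
load_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  rx <- list()
  for (r in j$reactions) {
    rx[[r$id]] <- list(id = r$id,
                       stoich = unlist(r$stoich),
                       lb = r$lb, ub = r$ub,
                       tags = as.character(unlist(r$tags)))
  }
  network_from_reactions(rx, j$exchange_map,
                         id = if (is.null(j$id)) "network" else j$id)
}

#' @rdname load_network
#' @param net a `metabolic_network`.
#' @export
write_network <- function(net, path) {
  rxs <- lapply(net$reactions, function(id) {
    st <- net$S[, id]
    st <- st[st != 0]
    list(id = id, stoich = as.list(st),
         lb = net$lb[[id]], ub = net$ub[[id]],
         tags = as.list(net$tags[[id]]))
  })
  jsonlite::write_json(
    list(id = net$id, metabolites = net$metabolites, reactions = rxs,
         exchange_map = as.list(net$exchange_map)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Minimal SBML Level 3 export / import
#'
#' Writes the network as an SBML Level 3 Version 1 document with the fbc
#' (flux balance constraints) bound attributes, covering the subset of SBML
#' this package produces: species, reactions with stoichiometric
#' speciesReferences, and per-reaction flux bounds. `read_sbml()` reads
#' documents written by `write_sbml()` (it is not a general SBML parser).
#'
#' @param net a `metabolic_network`.
#' @param path file path.
#' @return `write_sbml()` returns `path` invisibly; `read_sbml()` a
#'   `metabolic_network`.
#' @export
write_sbml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = net$id)
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in net$metabolites)
    xml2::xml_add_child(los, "species", id = m, compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (id in net$reactions) {
    rn <- xml2::xml_add_child(lor, "reaction", id = id, reversible =
                                tolower(as.character(net$lb[[id]] < 0)),
                              fast = "false")
    xml2::xml_set_attr(rn, "lb", format(net$lb[[id]], digits = 17))
    xml2::xml_set_attr(rn, "ub", format(net$ub[[id]], digits = 17))
    if (length(net$tags[[id]]))
      xml2::xml_set_attr(rn, "tags", paste(net$tags[[id]], collapse = ","))
    st <- net$S[, id]; st <- st[st != 0]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lrc <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs))
        xml2::xml_add_child(lrc, "speciesReference", species = m,
                            stoichiometry = format(-subs[[m]], digits = 17),
                            constant = "true")
    }
    if (length(prods)) {
      lpc <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods))
        xml2::xml_add_child(lpc, "speciesReference", species = m,
                            stoichiometry = format(prods[[m]], digits = 17),
                            constant = "true")
    }
  }
  em <- xml2::xml_add_child(model, "annotation")
  xml2::xml_set_attr(em, "exchange_map",
                     paste(names(net$exchange_map), net$exchange_map,
                           sep = ":", collapse = ";"))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_sbml
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  rx <- list()
  for (rn in xml2::xml_find_all(model, ".//s:reaction", ns)) {
    id <- xml2::xml_attr(rn, "id")
    st <- numeric()
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns))
      st[xml2::xml_attr(sr, "species")] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns))
      st[xml2::xml_attr(sr, "species")] <-
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    tags <- xml2::xml_attr(rn, "tags")
    rx[[id]] <- list(id = id, stoich = st,
                     lb = as.numeric(xml2::xml_attr(rn, "lb")),
                     ub = as.numeric(xml2::xml_attr(rn, "ub")),
                     tags = if (is.na(tags)) character() else
                       strsplit(tags, ",")[[1]])
  }
  emap_raw <- xml2::xml_attr(xml2::xml_find_first(model, ".//s:annotation", ns),
                             "exchange_map")
  pairs <- strsplit(strsplit(emap_raw, ";")[[1]], ":")
  emap <- stats::setNames(vapply(pairs, `[`, character(1), 2),
                          vapply(pairs, `[`, character(1), 1))
  network_from_reactions(rx, emap, id = xml2::xml_attr(model, "id"))
}
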
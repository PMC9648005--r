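#' Read a two-layer network model from disk
#'
#' Two formats are supported. `edge_table` is a plain TSV with columns
#' `source`, `target`, `sign` (`+`/`-`), `layer` (`fast`/`slow`) and
#' `provenance`, optionally accompanied by a YAML sidecar
#' (`<stem>.rules.yaml`) carrying the component table, combiner/saturation
#' overrides and input flags; the sidecar is what makes a round trip through
#' [write_network()] exact. `sbml_qual` is an SBML level-3 qual document in
#' which each layer of a component is one qualitative species named
#' `<id>__fast` / `<id>__slow` (the naming convention is a documented
#' assumption: the two update layers of one biological component are encoded
#' as two qualitative species distinguished by suffix).
#'
#' @param path file to read.
#' @param format `"edge_table"` or `"sbml_qual"`.
#' @param sidecar path to the YAML rules sidecar (edge_table only); defaults
#'   to `<path without extension>.rules.yaml` and is optional.
#' @return a validated [layered_network()].
#' @export
load_network <- function(path, format = c("edge_table", "sbml_qual"),
                         sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         edge_table = load_edge_table(path, sidecar),
         sbml_qual = load_sbml_qual(path))
}

#' Write a two-layer network model to disk
#'
#' Emits a file that round-trips through [load_network()] to an equal model
#' (same component set, interaction multiset and rule table). For
#' `edge_table`, a YAML sidecar `<stem>.rules.yaml` is always written next to
#' the TSV so that input flags, product combiners and saturation constants
#' survive the round trip.
#'
#' @inheritParams load_network
#' @param net a `layered_network`.
#' @return the main file path, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_table", "sbml_qual"),
                          sidecar = NULL) {
  format <- match.arg(format)
  validate_network(net)
  switch(format,
         edge_table = write_edge_table(net, path, sidecar),
         sbml_qual = write_sbml_qual(net, path))
  invisible(path)
}

sidecar_path <- function(path, sidecar) {
  sidecar %||% paste0(sub("\\.[^.]+$", "", path), ".rules.yaml")
}

load_edge_table <- function(path, sidecar = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("source", "target", "sign", "layer")
  if (!all(need %in% names(tab))) {
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  }
  side <- NULL
  sc <- sidecar_path(path, sidecar)
  if (file.exists(sc)) side <- yaml::read_yaml(sc)

  sat <- side$saturation_default %||% 1
  if (!is.null(side$components)) {
    comp <- do.call(rbind, lapply(side$components, function(x) {
      data.frame(id = x$id, role = x$role %||% "other_signaling",
                 has_fast = isTRUE(x$has_fast), has_slow = isTRUE(x$has_slow),
                 annotation = x$annotation %||% "", stringsAsFactors = FALSE)
    }))
  } else {
    ids <- unique(c(tab$source, tab$target))
    comp <- data.frame(id = ids, stringsAsFactors = FALSE)
  }

  rules <- NULL
  if (!is.null(side$rules)) {
    rules <- lapply(side$rules, function(x) {
      terms <- if (length(x$terms)) {
        do.call(rbind, lapply(x$terms, function(t) {
          data.frame(source = t$source, sign = t$sign, stringsAsFactors = FALSE)
        }))
      } else NULL
      update_rule(x$target, x$layer, terms, x$combiner %||% "additive",
                  x$saturation %||% sat)
    })
  }

  interactions <- if (nrow(tab)) tab else NULL
  layered_network(comp, interactions, rules,
                  metadata = side$metadata %||% list(),
                  saturation_default = sat)
}

write_edge_table <- function(net, path, sidecar = NULL) {
  tab <- net$interactions
  tab$sign <- ifelse(tab$sign > 0, "+", "-")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

  comp <- net$components
  side <- list(
    metadata = net$metadata,
    saturation_default = 1,
    components = lapply(seq_len(nrow(comp)), function(i) {
      list(id = comp$id[i], role = comp$role[i],
           has_fast = comp$has_fast[i], has_slow = comp$has_slow[i],
           annotation = comp$annotation[i])
    }),
    rules = lapply(unname(net$rules), function(r) {
      list(target = r$target, layer = r$layer, combiner = r$combiner,
           saturation = r$saturation,
           terms = lapply(seq_len(nrow(r$terms)), function(j) {
             list(source = r$terms$source[j], sign = as.integer(r$terms$sign[j]))
           }))
    })
  )
  yaml::write_yaml(side, sidecar_path(path, sidecar))
  path
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
CN_NS <- "https://chondronet.r-pkg/ns"

species_id <- function(id, layer) paste0(id, "__", layer)

split_species_id <- function(sid) {
  m <- regmatches(sid, regexec("^(.*)__(fast|slow)$", sid))[[1]]
  if (length(m) != 3) stop("qualitative species id '", sid,
                           "' does not follow the <component>__<layer> convention")
  list(id = m[2], layer = m[3])
}

write_sbml_qual <- function(net, path) {
  doc <- xml2::xml_new_root("sbml",
                            xmlns = SBML_NS, "xmlns:qual" = QUAL_NS,
                            "xmlns:cn" = CN_NS,
                            level = "3", version = "1", "qual:required" = "true")
  model <- xml2::xml_add_child(doc, "model",
                               id = gsub("[^A-Za-z0-9_]", "_",
                                         net$metadata$name %||% "chondronet_model"))
  lsp <- xml2::xml_add_child(model, "qual:listOfQualitativeSpecies")
  comp <- net$components
  for (i in seq_len(nrow(comp))) {
    for (layer in c("fast", "slow")) {
      if (!comp[[paste0("has_", layer)]][i]) next
      xml2::xml_add_child(lsp, "qual:qualitativeSpecies",
                          "qual:id" = species_id(comp$id[i], layer),
                          "qual:compartment" = "cell",
                          "qual:constant" = "false",
                          "qual:maxLevel" = "1",
                          "cn:role" = comp$role[i],
                          "cn:annotation" = comp$annotation[i])
    }
  }
  ltr <- xml2::xml_add_child(model, "qual:listOfTransitions")
  for (r in net$rules) {
    if (nrow(r$terms) == 0) next  # inputs have no transition
    prov <- vapply(seq_len(nrow(r$terms)), function(j) {
      sub <- net$interactions
      hit <- sub$source == r$terms$source[j] & sub$target == r$target &
        sub$layer == r$layer & sub$sign == r$terms$sign[j]
      if (any(hit)) sub$provenance[which(hit)[1]] else "curated"
    }, "")
    tr <- xml2::xml_add_child(ltr, "qual:transition",
                              "qual:id" = paste0("tr_", rule_key(r$target, r$layer)),
                              "cn:combiner" = r$combiner,
                              "cn:saturation" = format(r$saturation, digits = 15))
    lin <- xml2::xml_add_child(tr, "qual:listOfInputs")
    for (j in seq_len(nrow(r$terms))) {
      xml2::xml_add_child(lin, "qual:input",
                          "qual:qualitativeSpecies" =
                            species_id(r$terms$source[j], "fast"),
                          "cn:component" = r$terms$source[j],
                          "qual:sign" = if (r$terms$sign[j] > 0) "positive" else "negative",
                          "qual:transitionEffect" = "none",
                          "cn:provenance" = prov[j])
    }
    lout <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(lout, "qual:output",
                        "qual:qualitativeSpecies" = species_id(r$target, r$layer),
                        "qual:transitionEffect" = "assignmentLevel")
  }
  xml2::write_xml(doc, path)
  path
}

load_sbml_qual <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(sbml = SBML_NS, qual = QUAL_NS, cn = CN_NS)
  sp <- xml2::xml_find_all(doc, ".//qual:qualitativeSpecies", ns)
  if (length(sp) == 0) stop("no qualitative species found; not an SBML-qual file?")
  sp_info <- lapply(sp, function(s) {
    parts <- split_species_id(xml2::xml_attr(s, "qual:id", ns))
    c(parts, role = xml2::xml_attr(s, "cn:role", ns),
      annotation = xml2::xml_attr(s, "cn:annotation", ns))
  })
  ids <- unique(vapply(sp_info, `[[`, "", "id"))
  comp <- data.frame(id = ids, stringsAsFactors = FALSE)
  comp$has_fast <- comp$has_slow <- FALSE
  comp$role <- "other_signaling"
  comp$annotation <- ""
  for (s in sp_info) {
    i <- match(s$id, comp$id)
    comp[[paste0("has_", s$layer)]][i] <- TRUE
    if (!is.na(s$role)) comp$role[i] <- s$role
    if (!is.na(s$annotation)) comp$annotation[i] <- s$annotation
  }

  rules <- list()
  ints <- list()
  for (tr in xml2::xml_find_all(doc, ".//qual:transition", ns)) {
    out <- xml2::xml_find_first(tr, ".//qual:output", ns)
    tgt <- split_species_id(xml2::xml_attr(out, "qual:qualitativeSpecies", ns))
    inputs <- xml2::xml_find_all(tr, ".//qual:input", ns)
    terms <- do.call(rbind, lapply(inputs, function(inp) {
      src <- xml2::xml_attr(inp, "cn:component", ns)
      if (is.na(src)) {
        src <- split_species_id(xml2::xml_attr(inp, "qual:qualitativeSpecies", ns))$id
      }
      data.frame(source = src,
                 sign = if (identical(xml2::xml_attr(inp, "qual:sign", ns),
                                      "negative")) -1L else 1L,
                 provenance = xml2::xml_attr(inp, "cn:provenance", ns),
                 stringsAsFactors = FALSE)
    }))
    terms$provenance[is.na(terms$provenance)] <- "curated"
    comb <- xml2::xml_attr(tr, "cn:combiner", ns)
    sat <- xml2::xml_attr(tr, "cn:saturation", ns)
    key <- rule_key(tgt$id, tgt$layer)
    if (!is.null(rules[[key]])) stop("duplicate transition for ", key)
    rules[[key]] <- update_rule(tgt$id, tgt$layer, terms[, c("source", "sign")],
                                if (is.na(comb)) "additive" else comb,
                                if (is.na(sat)) 1 else as.numeric(sat))
    ints[[length(ints) + 1]] <- data.frame(source = terms$source, target = tgt$id,
                                           sign = terms$sign, layer = tgt$layer,
                                           provenance = terms$provenance,
                                           stringsAsFactors = FALSE)
  }
  interactions <- if (length(ints)) do.call(rbind, ints) else NULL
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  nm <- if (!inherits(mdl, "xml_missing")) xml2::xml_attr(mdl, "id") else NULL
  layered_network(comp, interactions, rules,
                  metadata = if (is.null(nm)) list() else list(name = nm))
}
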
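#' Path to a bundled pathway definition
#'
#' Two atom-resolved biosynthesis networks ship with the package:
#' `"nucleotide"` (methyl carbon entry via methyl-H4SPT, acetyl-CoA/pyruvate
#' synthesis, gluconeogenesis and the reverse ribulose-monophosphate route to
#' ribose-5-phosphate, and the pyrimidine and purine ring assemblies) and
#' `"lipid"` (the mevalonate pathway from acetyl-CoA through IPP/DMAPP to
#' geranylgeranyl diphosphate and the phytanyl chain of archaeal ether
#' lipids).
#'
#' @param which `"nucleotide"` or `"lipid"`.
#' @return Absolute file path to the bundled JSON definition.
#' @export
pathway_file <- function(which = c("nucleotide", "lipid")) {
  which <- match.arg(which)
  fname <- switch(which,
    nucleotide = "nucleotide_biosynthesis.json",
    lipid = "isoprenoid_lipid_biosynthesis.json"
  )
  path <- system.file("extdata", "pathways", fname, package = "misosip")
  if (path == "") stop("bundled pathway file not found: ", fname, call. = FALSE)
  path
}

#' Load and validate a pathway definition
#'
#' A pathway definition is a JSON document describing a directed acyclic
#' reaction network with per-atom carbon maps:
#' \preformatted{
#' {
#'   "sources":   ["MEOH", "DIC"],
#'   "compounds": [{"name": "...", "n_carbons": k}, ...],
#'   "reactions": [{"product": "...",
#'                  "assignments": [["compound", idx] | "SOURCE", ...],
#'                  "lost": [["compound", idx], ...],
#'                  "note": "..."}, ...]
#' }
#' }
#' Each product carbon is assigned exactly once, either to a reactant atom
#' (1-based index) or directly to a source pool. `lost` lists reactant atoms
#' not carried into the product (e.g. a decarboxylation). Validation checks:
#' every compound is produced by exactly one reaction; all referenced
#' compounds/atoms exist; the reference multiset of every reaction closes to
#' whole copies of each consumed reactant (carbon conservation; a reactant
#' atom referenced twice implies two equivalents consumed, as in the two
#' formyl units of a purine ring); and the compound dependency graph is
#' acyclic.
#'
#' @param path file path to a pathway JSON document.
#' @return An object of class `pathway_graph` with elements `sources`,
#'   `compounds` (named integer vector of carbon counts), `reactions`, and
#'   `order` (a topological order of compound names).
#' @export
load_pathway <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("sources", "compounds", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("pathway schema error: missing top-level field '", field, "'",
           call. = FALSE)
    }
  }
  sources <- vapply(doc$sources, as.character, character(1))
  if (anyDuplicated(sources)) {
    stop("pathway schema error: duplicated source ids", call. = FALSE)
  }

  cmp_names <- vapply(doc$compounds, function(x) as.character(x$name), character(1))
  n_carbons <- vapply(doc$compounds, function(x) as.integer(x$n_carbons), integer(1))
  if (anyDuplicated(cmp_names)) {
    stop("pathway schema error: duplicated compound names", call. = FALSE)
  }
  if (any(n_carbons < 1)) {
    stop("pathway schema error: compounds need >= 1 carbon", call. = FALSE)
  }
  if (any(cmp_names %in% sources)) {
    stop("pathway schema error: compound name collides with a source id",
         call. = FALSE)
  }
  compounds <- stats::setNames(n_carbons, cmp_names)

  products <- vapply(doc$reactions, function(r) as.character(r$product), character(1))
  if (anyDuplicated(products)) {
    stop("pathway schema error: compound produced by more than one reaction: ",
         paste(unique(products[duplicated(products)]), collapse = ", "),
         call. = FALSE)
  }
  missing_prod <- setdiff(cmp_names, products)
  if (length(missing_prod)) {
    stop("pathway schema error: compounds never produced: ",
         paste(missing_prod, collapse = ", "), call. = FALSE)
  }

  reactions <- lapply(doc$reactions, function(r) {
    prod <- as.character(r$product)
    label <- paste0("reaction producing '", prod, "'")
    if (!prod %in% cmp_names) {
      stop("pathway schema error: unknown product in ", label, call. = FALSE)
    }
    asg <- r$assignments
    if (length(asg) != compounds[[prod]]) {
      stop("pathway schema error: ", label, " assigns ", length(asg),
           " atoms but the compound has ", compounds[[prod]], call. = FALSE)
    }
    parse_ref <- function(a, what) {
      if (is.character(a) && length(a) == 1) {
        if (!a %in% sources) {
          stop("pathway schema error: unknown source id '", a, "' in ", label,
               call. = FALSE)
        }
        return(list(kind = "source", id = a))
      }
      if (is.list(a) && length(a) == 2) {
        cmp <- as.character(a[[1]]); idx <- as.integer(a[[2]])
        if (!cmp %in% cmp_names) {
          stop("pathway schema error: unknown reactant '", cmp, "' in ", label,
               call. = FALSE)
        }
        if (is.na(idx) || idx < 1 || idx > compounds[[cmp]]) {
          stop("pathway schema error: atom index ", a[[2]], " out of range for '",
               cmp, "' in ", label, call. = FALSE)
        }
        return(list(kind = "atom", compound = cmp, idx = idx))
      }
      stop("pathway schema error: malformed ", what, " entry in ", label,
           call. = FALSE)
    }
    assignments <- lapply(asg, parse_ref, what = "assignment")
    lost <- lapply(r$lost %||% list(), parse_ref, what = "lost-atom")
    if (any(vapply(lost, function(x) x$kind == "source", logical(1)))) {
      stop("pathway schema error: lost atoms must reference reactant atoms in ",
           label, call. = FALSE)
    }
    # conservation: references must close to whole copies of each reactant
    refs <- c(Filter(function(x) x$kind == "atom", assignments), lost)
    if (length(refs)) {
      by_cmp <- split(vapply(refs, `[[`, integer(1), "idx"),
                      vapply(refs, `[[`, character(1), "compound"))
      for (cmp in names(by_cmp)) {
        counts <- tabulate(by_cmp[[cmp]], nbins = compounds[[cmp]])
        if (length(unique(counts)) != 1 || counts[1] < 1) {
          stop("pathway schema error: carbon not conserved in ", label,
               ": reactant '", cmp, "' atoms referenced unevenly (",
               paste(counts, collapse = ","), ")", call. = FALSE)
        }
      }
    }
    list(product = prod, assignments = assignments, lost = lost,
         note = r$note %||% "")
  })

  # acyclicity and evaluation order via the compound dependency graph
  edges <- do.call(rbind, lapply(reactions, function(r) {
    deps <- unique(vapply(Filter(function(x) x$kind == "atom", r$assignments),
                          `[[`, character(1), "compound"))
    if (!length(deps)) return(NULL)
    cbind(deps, r$product)
  }))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(cmp_names)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  if (!igraph::is_dag(g)) {
    stop("pathway schema error: reaction network contains a cycle", call. = FALSE)
  }
  order <- igraph::as_ids(igraph::topo_sort(g, mode = "out"))

  structure(
    list(sources = sources, compounds = compounds,
         reactions = stats::setNames(reactions, products), order = order),
    class = "pathway_graph"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pathway_graph <- function(x, ...) {
  cat("Pathway graph:", length(x$compounds), "compounds,",
      length(x$reactions), "reactions, sources:",
      paste(x$sources, collapse = ", "), "\n")
  invisible(x)
}

#' Propagate carbon-source provenance through a pathway
#'
#' Walks the reactions in topological order; each product carbon inherits the
#' provenance vector (fraction of that atom stemming from each source pool)
#' of the reactant atom it maps to, or a pure unit vector when it is drawn
#' directly from a source. Purely stoichiometric atom accounting: no fluxes,
#' no fractionation.
#'
#' @param graph a [load_pathway()] result.
#' @return An object of class `provenance_result`: `atoms` is a named list of
#'   per-compound matrices (rows = carbon atoms, columns = sources), and
#'   `aggregate` a compounds-by-sources matrix of atom-averaged fractions.
#' @export
propagate <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ns <- length(graph$sources)
  atoms <- list()
  for (cmp in graph$order) {
    rxn <- graph$reactions[[cmp]]
    m <- matrix(0, nrow = graph$compounds[[cmp]], ncol = ns,
                dimnames = list(NULL, graph$sources))
    for (i in seq_along(rxn$assignments)) {
      a <- rxn$assignments[[i]]
      m[i, ] <- if (a$kind == "source") {
        as.numeric(graph$sources == a$id)
      } else {
        atoms[[a$compound]][a$idx, ]
      }
    }
    atoms[[cmp]] <- m
  }
  aggregate <- t(vapply(atoms, colMeans, numeric(ns)))
  structure(list(atoms = atoms, aggregate = aggregate, sources = graph$sources),
            class = "provenance_result")
}

#' @export
print.provenance_result <- function(x, ...) {
  cat("Carbon provenance (atom-averaged source fractions):\n")
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Aggregate source fraction of one compound
#'
#' @param result a [propagate()] result.
#' @param compound compound name.
#' @param source source pool id (e.g. `"MEOH"` or `"DIC"`).
#' @return Fraction of the compound's carbon stemming from `source`.
#' @export
compound_source_fraction <- function(result, compound, source) {
  stopifnot(inherits(result, "provenance_result"))
  if (!compound %in% rownames(result$aggregate)) {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  if (!source %in% result$sources) {
    stop("unknown source: ", source, call. = FALSE)
  }
  result$aggregate[compound, source]
}

#' Predict the 13C atom fraction of a biosynthesized compound
#'
#' Under any labeling scheme, the expected atom fraction of a compound is the
#' provenance-weighted mean of the source pool atom fractions,
#' `F_compound = sum_s p_s * F_s` (affine in each source F; equal pool
#' compositions return that common value). Links the provenance model to
#' lipid- and RNA-SIP observables.
#'
#' @param result a [propagate()] result.
#' @param compound compound name.
#' @param pool_fractions named numeric, 13C atom fraction per source pool;
#'   must cover all sources of the pathway.
#' @return Predicted 13C atom fraction.
#' @export
predict_fraction_13c <- function(result, compound, pool_fractions) {
  stopifnot(inherits(result, "provenance_result"))
  missing <- setdiff(result$sources, names(pool_fractions))
  if (length(missing)) {
    stop("missing source pool fraction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!compound %in% rownames(result$aggregate)) {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  sum(result$aggregate[compound, result$sources] *
        unlist(pool_fractions)[result$sources])
}

#' Carbon-weighted source fraction of a macromolecule
#'
#' Combines compound-level provenance into a macromolecule-level fraction,
#' weighting each building block by its carbon count times its multiplicity
#' (e.g. a purine ribonucleotide = one ribose + one purine base).
#'
#' @param result a [propagate()] result.
#' @param composition data.frame with columns `compound` and `count`
#'   (positive integers), or a named numeric vector of counts.
#' @param source source pool id (default `"MEOH"`).
#' @return Carbon-weighted mean source fraction.
#' @export
aggregate_macromolecule <- function(result, composition, source = "MEOH") {
  stopifnot(inherits(result, "provenance_result"))
  if (is.numeric(composition) && !is.null(names(composition))) {
    composition <- data.frame(compound = names(composition),
                              count = as.numeric(composition))
  }
  if (!is.data.frame(composition) || nrow(composition) == 0) {
    stop("empty composition", call. = FALSE)
  }
  stopifnot(all(c("compound", "count") %in% names(composition)),
            all(composition$count >= 1))
  n_atoms <- vapply(composition$compound, function(cmp) {
    if (!cmp %in% names(result$atoms)) stop("unknown compound: ", cmp, call. = FALSE)
    nrow(result$atoms[[cmp]])
  }, numeric(1))
  fr <- vapply(composition$compound, compound_source_fraction, numeric(1),
               result = result, source = source)
  w <- composition$count * n_atoms
  sum(w * fr) / sum(w)
}
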
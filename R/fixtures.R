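#' Packaged network fixtures
#'
#' Small reference networks used throughout the package's tests, examples
#' and documentation:
#' \describe{
#'   \item{`fig1a`}{three genes, five edges (`A->A`, `A->B`, `B->A`,
#'     `A->C`, `C->B`), hence three directed cycles (`A->A`, `A->B->A`,
#'     `A->C->B->A`); gene `A` alone is the minimum FVS.}
#'   \item{`fig1e`}{a five-node acyclic cascade; its FVS is empty and its
#'     dynamics converges on a unique, globally stable equilibrium.}
#'   \item{`fig1f`}{three nodes, two cycles (`a<->b` and `a->c->a`) sharing
#'     node `a`, so `{a}` is the minimum FVS while the dynamics is
#'     bistable — the minimal setting in which clamping one node switches
#'     the system between two steady states.}
#'   \item{`toggle`}{two mutually repressing genes, the canonical bistable
#'     switch.}
#'   \item{`ciona`}{a synthetic stand-in for the ascidian (Ciona
#'     intestinalis type A) cell-fate specification network, shipped as
#'     `extdata/ciona_grn_synthetic.tsv`. It reproduces the published
#'     summary topology of that network — 92 nodes, 328 edges, minimum FVS
#'     size 5, and exactly 12 minimum FVSs factorizing as
#'     \{Foxa.a|Nodal|Snail\} x \{Foxd|Twist-r.a/b\} x \{Neurog|Delta.b\} x
#'     \{Zic-r.b\} x \{Erk signaling\} — but its non-feedback wiring is
#'     generated, not curated from the original supplementary table (see
#'     the header of the fixture file). The fixture also carries the
#'     conventional A/D/N/Z/E condition-code letters and the
#'     tissue-marker panel.}
#' }
#'
#' @param key one of `"fig1a"`, `"fig1e"`, `"fig1f"`, `"toggle"`, `"ciona"`
#' @return object of class `network_fixture`: list with `key`, `network`,
#'   `provenance`, and for `ciona` also `fvs_nodes` (the conventional FVS
#'   choice, scan order), `letters` (its code letters) and `panel`
#'   (a [marker_panel]).
#' @export
get_fixture <- function(key = c("fig1a", "fig1e", "fig1f", "toggle", "ciona")) {
  key <- match.arg(key)
  fx <- switch(key,
    fig1a = list(
      network = regulatory_network(
        nodes = c("A", "B", "C"),
        edges = data.frame(
          source = c("A", "A", "B", "A", "C"),
          target = c("A", "B", "A", "C", "B"),
          sign = "activating", stringsAsFactors = FALSE),
        name = "fig1a"),
      provenance = "Three-gene toy network with cycles A->A, A->B->A, A->C->B->A."),
    fig1e = list(
      network = regulatory_network(
        nodes = c("p", "q", "r", "s", "t"),
        edges = data.frame(
          source = c("p", "q", "r", "r", "s"),
          target = c("r", "r", "s", "t", "t"),
          sign = "activating", stringsAsFactors = FALSE),
        name = "fig1e"),
      provenance = "Acyclic five-node cascade; empty FVS, globally stable equilibrium."),
    fig1f = list(
      network = regulatory_network(
        nodes = c("a", "b", "c"),
        edges = data.frame(
          source = c("b", "a", "a", "c"),
          target = c("a", "b", "c", "a"),
          sign = "activating", stringsAsFactors = FALSE),
        name = "fig1f"),
      provenance = paste(
        "Two cycles (a<->b, a->c->a) sharing node a; FVS = {a}.",
        "Wiring chosen consistent with that description, not a verbatim copy.")),
    toggle = list(
      network = regulatory_network(
        nodes = c("u", "v"),
        edges = data.frame(
          source = c("u", "v"), target = c("v", "u"),
          sign = "repressing", stringsAsFactors = FALSE),
        name = "toggle"),
      provenance = "Two mutually repressing genes; canonical bistable switch."),
    ciona = {
      path <- system.file("extdata", "ciona_grn_synthetic.tsv",
                          package = "fvscontrol", mustWork = TRUE)
      list(
        network = load_network(path, "edgelist_tsv", name = "ciona"),
        provenance = paste(
          "Synthetic stand-in for the Ciona intestinalis (type A) cell-fate",
          "GRN (92 nodes, 328 edges); feedback structure engineered to yield",
          "the published minimum-FVS family; see the fixture file header."),
        fvs_nodes = c("Foxa.a", "Foxd", "Neurog", "Zic-r.b", "Erk_signaling"),
        letters = c("A", "D", "N", "Z", "E"),
        panel = ciona_marker_panel())
    })
  structure(c(list(key = key), fx), class = "network_fixture")
}

#' @export
print.network_fixture <- function(x, ...) {
  cat(sprintf("<network_fixture> %s\n", x$key))
  print(x$network)
  cat(strwrap(x$provenance, indent = 2, exdent = 2), sep = "\n")
  invisible(x)
}

#' Tissue-marker panel for the ciona fixture
#'
#' One RT-qPCR-style marker per tissue, with the brain panel extending the
#' pan-neural one (brain = Bco + Celf3.a, nerve cord = Celf3.a alone) so
#' that the subset rule of [classify_readout] reads a brain+pan-neural
#' pattern as brain.
#'
#' @param tau activity threshold as a fraction of maximum (default 0.5)
#' @return a [marker_panel]
#' @export
ciona_marker_panel <- function(tau = 0.5) {
  marker_panel(list(
    epidermis = "Epi1",
    brain = c("Bco", "Celf3.a"),
    nerve_cord = "Celf3.a",
    endoderm = "Alp",
    notochord = "Noto1",
    mesenchyme = "Fli.Erg.a",
    muscle = "Myl"
  ), tau = tau)
}
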
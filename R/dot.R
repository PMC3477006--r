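## Graphviz DOT export with the profile's notational conventions: entity
## classes as nodes labeled with their stereotype, is_a drawn like a UML
## generalization (hollow triangle), the part_of family like a UML shared
## aggregation (open diamond at the whole end), and every other relation
## as a labeled directed edge.

.dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

.part_family <- c("part_of", "proper_part_of", "integral_part_of")
.has_part_family <- c("has_part", "has_proper_part", "has_integral_part")

#' Export a model as Graphviz DOT
#'
#' Emits a deterministic DOT digraph: one node per class (sorted by id)
#' labeled `"name\n<<kind>>"` (unstereotyped classes get just the name),
#' `is_a` edges with hollow-triangle arrowheads as in a UML
#' generalization, part-of-family edges with an open diamond at the whole
#' end as in a UML shared aggregation, and all other kinds as directed
#' edges labeled `<<relation_name>>`.  Edges are sorted by kind, source,
#' target, so output is byte-identical across runs on the same model.
#'
#' @param model An [OntologyModel].
#' @param name Graph name.
#' @return Character vector of DOT lines.
#' @examples
#' cat(head(toDot(proFragment()), 5), sep = "\n")
#' @export
toDot <- function(model, name = "ontology") {
    cl <- model@classes[order(model@classes$id), , drop = FALSE]
    rel <- model@relations
    rel <- rel[order(rel$kind, rel$source, rel$target), , drop = FALSE]
    lines <- c(paste0("digraph ", .dot_quote(name), " {"),
               "  node [shape=box];")
    for (i in seq_len(nrow(cl))) {
        lab <- if (cl$kind[i] == "UNKNOWN") cl$name[i]
               else paste0(cl$name[i], "\\n<<", tolower(cl$kind[i]), ">>")
        lines <- c(lines, paste0("  ", .dot_quote(cl$id[i]),
                                 " [label=", .dot_quote(lab), "];"))
    }
    for (i in seq_len(nrow(rel))) {
        k <- rel$kind[i]
        e <- paste0("  ", .dot_quote(rel$source[i]), " -> ",
                    .dot_quote(rel$target[i]))
        attr <- if (k == "is_a") {
            "[arrowhead=empty]"     # UML generalization
        } else if (k %in% .part_family) {
            ## open diamond at the whole (target) end, shared aggregation
            paste0("[arrowhead=odiamond, label=", .dot_quote(
                paste0("<<", k, ">>")), "]")
        } else if (k %in% .has_part_family) {
            ## the whole is the source; diamond at the source end
            paste0("[dir=back, arrowtail=odiamond, label=", .dot_quote(
                paste0("<<", k, ">>")), "]")
        } else {
            paste0("[label=", .dot_quote(paste0("<<", k, ">>")), "]")
        }
        lines <- c(lines, paste(e, attr, ";"))
    }
    c(lines, "}")
}
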
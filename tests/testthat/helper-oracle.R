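# Independent brute-force evaluator of the relation endpoint rules,
# written against the rules' prose statements and deliberately sharing no
# code or data structures with the engine.  Each rule row is a compact
# string: "src|tgt|branch|conds|irrefl" where src/tgt are P/C/M/I/- kind
# bounds, branch is B (same branch required) or -, conds names the
# conditional set (po = material-part/immaterial-whole, hp = its mirror,
# eq = is_a specification parity) and irrefl is R or -.

oracle_rules <- c(
    is_a              = "-|-|B|eq|-",
    part_of           = "-|-|B|po|-",
    proper_part_of    = "-|-|B|po|R",
    integral_part_of  = "-|-|B|po|-",
    has_part          = "-|-|B|hp|-",
    has_proper_part   = "-|-|B|hp|R",
    has_integral_part = "-|-|B|hp|-",
    located_in        = "C|C|-|-|-",
    location_of       = "C|C|-|-|-",
    adjacent_to       = "C|C|-|-|-",
    contained_in      = "M|I|-|-|-",
    contains          = "I|M|-|-|-",
    derives_from      = "M|M|-|-|-",
    derived_into      = "M|M|-|-|-",
    transformation_of = "M|M|-|-|-",
    preceded_by       = "P|P|-|-|-",
    precedes          = "P|P|-|-|-",
    has_participant   = "P|C|-|-|-",
    participates_in   = "C|P|-|-|-",
    has_agent         = "P|M|-|-|-",
    agent_in          = "M|P|-|-|-"
)

# is `kind` at or below `bound` (single letters, "-" = no bound)?
oracle_below <- function(kind, bound) {
    if (bound == "-") return(TRUE)
    ups <- list(P = "P", C = "C", M = c("M", "C"), I = c("I", "C"))
    bound %in% c(kind, ups[[kind]])
}

oracle_pair_valid <- function(kind, sk, tk) {
    f <- strsplit(oracle_rules[[kind]], "|", fixed = TRUE)[[1]]
    if (!oracle_below(sk, f[1]) || !oracle_below(tk, f[2])) return(FALSE)
    if (f[3] == "B") {
        same <- (sk == "P" && tk == "P") ||
            (sk %in% c("C", "M", "I") && tk %in% c("C", "M", "I"))
        if (!same) return(FALSE)
    }
    if (f[4] == "po") {
        if (sk == "M" && tk != "M") return(FALSE)
        if (tk == "I" && sk != "I") return(FALSE)
    }
    if (f[4] == "hp") {
        if (tk == "M" && sk != "M") return(FALSE)
        if (sk == "I" && tk != "I") return(FALSE)
    }
    if (f[4] == "eq") {
        if (sk %in% c("C", "M", "I") && tk %in% c("C", "M", "I") &&
            sk != tk) return(FALSE)
    }
    TRUE
}

# all valid (source, target) kind pairs of a relation over the 16
# declarable combinations, in full kind names
oracle_valid_pairs <- function(kind) {
    short <- c(P = "PROCESS", C = "CONTINUANT", M = "MATERIAL",
               I = "IMMATERIAL")
    out <- data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE)
    for (s in names(short)) for (t in names(short))
        if (oracle_pair_valid(kind, s, t))
            out <- rbind(out, data.frame(source = short[[s]],
                                         target = short[[t]],
                                         stringsAsFactors = FALSE))
    out
}

# convenience: matrix of validity over the 4x4 kind grid
oracle_matrix <- function(kind) {
    ks <- c("P", "C", "M", "I")
    outer(ks, ks, Vectorize(function(s, t) oracle_pair_valid(kind, s, t)))
}

engine_matrix <- function(kind) {
    ks <- c(P = "PROCESS", C = "CONTINUANT", M = "MATERIAL",
            I = "IMMATERIAL")
    vp <- validKindPairs(kind)
    outer(names(ks), names(ks), Vectorize(function(s, t)
        any(vp$source == ks[[s]] & vp$target == ks[[t]])))
}
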
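# Classed conditions so callers can distinguish failure modes.
sam_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "sam_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# InvalidStructure: unparsable or valence-violating input structure.
# UnknownUnits: activity value in a unit outside the accepted set.
# DuplicateStructure: two input compounds share a canonical key.
# MissingPotency: a pair member lacks a potency for the pair's context.
# SizeLimit: a molecule exceeds the exhaustive oracle's size bound.
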
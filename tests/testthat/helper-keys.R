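# Small keys built in code, shared across test files.

toy_characters <- paste(
  "char_id\tlabel\tkind\tstates\tunits\tsymbol\tdescription",
  "color\tleaf color\tcategorical\tred,blue\t\t\t",
  "size\tleaf size\tquantitative\t\tcm\t\t",
  "spots\tspots\tbinary\t\t\t\t",
  sep = "\n")

# 3 taxa over 2 couplets
toy_couplets <- paste(
  "couplet\tslot\tstatement\tpredicates\ttarget",
  "1\ta\tLeaves red\tcolor=red\tC:2",
  "1\tb\tLeaves blue\tcolor=blue\tT:B#1",
  "2\ta\tLeaves small\tsize<5\tT:A#1",
  "2\tb\tLeaves large\tsize>=5\tT:C#1",
  sep = "\n")

toy_key <- function() parse_key(toy_characters, toy_couplets)

# minimal 2-taxon key, used for the Newick shape check
pair_key <- function() parse_key(toy_characters, paste(
  "couplet\tslot\tstatement\tpredicates\ttarget",
  "1\ta\tLeaves red\tcolor=red\tT:A#1",
  "1\tb\tLeaves blue\tcolor=blue\tT:B#1",
  sep = "\n"))

# four taxa split 2/2 by a binary character, then separated pairwise
quad_characters <- paste(
  "char_id\tlabel\tkind\tstates\tunits\tsymbol\tdescription",
  "c1\tsplit\tbinary\t\t\t\t",
  "c2\tleft\tbinary\t\t\t\t",
  "c3\tright\tbinary\t\t\t\t",
  "c4\tuseless\tbinary\t\t\t\t",
  sep = "\n")
quad_couplets <- paste(
  "couplet\tslot\tstatement\tpredicates\ttarget",
  "1\ta\tc1 present\tc1=present\tC:2",
  "1\tb\tc1 absent\tc1=absent\tC:3",
  "2\ta\tc2 present\tc2=present\tT:A#1",
  "2\tb\tc2 absent\tc2=absent\tT:B#1",
  "3\ta\tc3 present\tc3=present\tT:C#1",
  "3\tb\tc3 absent\tc3=absent\tT:D#1",
  sep = "\n")
quad_key <- function() parse_key(quad_characters, quad_couplets)

syagrus <- local({
  key <- NULL
  function() {
    if (is.null(key)) key <<- load_fixture("syagrus_key")
    key
  }
})

lytocaryum_group <- c("S. itapebiensis", "S. weddelliana", "S. hoehnei",
                      "S. insignis")
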
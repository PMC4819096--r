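# Shared fixtures, built in code.

tree_8taxa <- function(b = 0.1) {
  txt <- sprintf(paste0(
    "(((t1:%1$g,t2:%1$g):%1$g,(t3:%1$g,t4:%1$g):%1$g):%2$g,",
    "((t5:%1$g,t6:%1$g):%1$g,(t7:%1$g,t8:%1$g):%1$g):%2$g);"), b, b / 2)
  ape::read.tree(text = txt)
}

tree_3taxa <- function() {
  ape::read.tree(text = "((a:0.2,b:0.3):0.1,c:0.4);")
}

tree_6taxa <- function() {
  ape::read.tree(
    text = "((a:0.15,b:0.15):0.1,(c:0.15,d:0.15):0.1,(e:0.2,f:0.2):0.05);")
}

# small hand-made expression table
toy_expression <- function() {
  data.frame(
    probe_id = paste0("p", 1:6),
    gene_symbol = c("VGF", "CALR", "HTRA1", "MANF", "IGFBP2", "XBP1"),
    p_raw = c(1e-10, 1e-9, 0.0005, 0.02, 1e-12, 0.5),
    p_adj = c(6e-10, 3e-9, 0.001, 0.03, 1.2e-11, 0.5),
    log_fc = c(-2.1, 1.5, -0.8, 0.3, -3.0, 0.1))
}
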
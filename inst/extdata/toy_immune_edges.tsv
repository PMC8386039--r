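leukocyte	cell
epithelial cell	cell
stromal cell	cell
lymphocyte	leukocyte
myeloid leukocyte	leukocyte
T cell	lymphocyte
B cell	lymphocyte
natural killer cell	lymphocyte
CD4 T cell	T cell
CD8 T cell	T cell
regulatory T cell	T cell
gamma-delta T cell	T cell
naive B cell	B cell
memory B cell	B cell
plasma cell	B cell
monocyte	myeloid leukocyte
macrophage	myeloid leukocyte
dendritic cell	myeloid leukocyte
neutrophil	myeloid leukocyte
basophil	myeloid leukocyte
eosinophil	myeloid leukocyte
alveolar macrophage	macrophage
inflammatory macrophage	macrophage
classical monocyte	monocyte
non-classical monocyte	monocyte
secretory cell	epithelial cell
ciliated cell	epithelial cell
fibroblast	stromal cell
endothelial cell	stromal cell
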
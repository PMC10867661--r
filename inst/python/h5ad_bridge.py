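"""Plain-text <-> h5ad converter used by the R package.

The R side writes/reads an exchange directory (MatrixMarket matrices plus
TSV tables, genes x cells); this script converts it to/from an AnnData
h5ad file (cells x genes in X, labels in obs["cell_type"], extra matrices
as layers). Kept dependency-minimal: anndata, scipy, pandas, numpy.
"""

import argparse
import os
import sys

import numpy as np
import pandas as pd
import scipy.io as sio
import scipy.sparse as sp
import anndata as ad

def pack(exchange_dir, out_path):
    X = sio.mmread(os.path.join(exchange_dir, "X.mtx"))  # genes x cells
    X = sp.csr_matrix(X.T)  # cells x genes
    var = pd.read_csv(os.path.join(exchange_dir, "var.tsv"), sep="\t",
                      dtype=str)
    obs = pd.read_csv(os.path.join(exchange_dir, "obs.tsv"), sep="\t",
                      dtype=str)
    var.index = var.pop("gene_id")
    obs.index = obs.pop("cell_id")
    var.index.name = None
    obs.index.name = None
    adata = ad.AnnData(X=X, obs=obs, var=var)
    for fn in sorted(os.listdir(exchange_dir)):
        if fn.startswith("layer_") and fn.endswith(".mtx"):
            layer = fn[len("layer_"):-len(".mtx")]
            m = sp.csr_matrix(sio.mmread(os.path.join(exchange_dir, fn)).T)
            if layer == "dropout_mask":
                m = m.astype(bool)
            adata.layers[layer] = m
    adata.write_h5ad(out_path)


def unpack(in_path, exchange_dir):
    os.makedirs(exchange_dir, exist_ok=True)
    adata = ad.read_h5ad(in_path)
    X = adata.X
    if not sp.issparse(X):
        X = sp.csr_matrix(np.asarray(X))
    sio.mmwrite(os.path.join(exchange_dir, "X.mtx"), X.T.tocoo())
    pd.DataFrame({"gene_id": adata.var_names}).to_csv(
        os.path.join(exchange_dir, "var.tsv"), sep="\t", index=False)
    obs = pd.DataFrame({"cell_id": adata.obs_names})
    if "cell_type" in adata.obs.columns:
        obs["cell_type"] = np.asarray(adata.obs["cell_type"].astype(str))
    obs.to_csv(os.path.join(exchange_dir, "obs.tsv"), sep="\t", index=False)
    for layer in adata.layers.keys():
        m = adata.layers[layer]
        if not sp.issparse(m):
            m = sp.csr_matrix(np.asarray(m))
        m = m.astype(np.int64 if layer == "dropout_mask" else np.float64)
        sio.mmwrite(
            os.path.join(exchange_dir, f"layer_{layer}.mtx"), m.T.tocoo())


def main(argv=None):
    parser = argparse.ArgumentParser(description=__doc__)
    sub = parser.add_subparsers(dest="cmd", required=True)
    p = sub.add_parser("pack", help="exchange dir -> h5ad")
    p.add_argument("--dir", required=True)
    p.add_argument("--out", required=True)
    u = sub.add_parser("unpack", help="h5ad -> exchange dir")
    u.add_argument("--in", dest="inp", required=True)
    u.add_argument("--dir", required=True)
    args = parser.parse_args(argv)
    try:
        if args.cmd == "pack":
            pack(args.dir, args.out)
        else:
            unpack(args.inp, args.dir)
    except Exception as exc:  # surface the offending field to the R side
        sys.stderr.write(f"h5ad bridge error: {exc}\n")
        return 1
    return 0


if __name__ == "__main__":
    raise SystemExit(main())
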
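"""Generate R/ideal-bases-data.R: idealized nucleotide geometries in a
glycosidic-N base reference frame, plus Watson-Crick pair transforms.

Requires biotite (bundled chemical component dictionary) and scipy.
Run from the repository root:  python tools/make_ideal_bases.py
"""
import numpy as np
from scipy.optimize import least_squares
import biotite.structure.info as info

BACKBONE = {"P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
            "C2'", "C1'", "H5'", "H5''", "H4'", "H3'", "H2'", "H2''", "H1'",
            "HO3'", "HO5'"}
DROP = {"OP3", "HOP3", "HOP2"}  # 5'-terminal variants

def frame(coord, names, purine):
    idx = {n: i for i, n in enumerate(names)}
    n = coord[idx["N9" if purine else "N1"]]
    a1 = coord[idx["C4" if purine else "C2"]]
    a2 = coord[idx["C8" if purine else "C6"]]
    u1 = (a1 - n) / np.linalg.norm(a1 - n)
    u2 = (a2 - n) / np.linalg.norm(a2 - n)
    x = -(u1 + u2); x /= np.linalg.norm(x)
    z = np.cross(u1, u2); z /= np.linalg.norm(z)
    y = np.cross(z, x)
    R = np.column_stack([x, y, z])
    out = (coord - n) @ R
    # sanity: C1' lies along +x
    assert out[idx["C1'"]][0] > 0, "C1' not on +x side"
    return out

bases = {}
for code, letter, purine in [("DA", "A", True), ("DC", "C", False),
                             ("DG", "G", True), ("DT", "T", False)]:
    r = info.residue(code)
    keep = [i for i, nm in enumerate(r.atom_name) if nm not in DROP]
    names = [r.atom_name[i] for i in keep]
    elem = [r.element[i] for i in keep]
    coord = frame(r.coord[keep], names, purine)
    is_base = [nm not in BACKBONE for nm in names]
    bases[letter] = dict(names=names, elem=elem, coord=coord, is_base=is_base)

def get(letter, name):
    b = bases[letter]
    return b["coord"][b["names"].index(name)]

# Watson-Crick pair transform: complement placed in the forward base's frame as
#   y_paired = Rz(theta) @ diag(1,-1,-1) @ y_ideal + [tx, ty, 0]
# fitted to canonical heavy-atom H-bond distances + C1'-C1' separation.
TARGETS = {
    "A": [("N1", "N3", 2.82), ("N6", "O4", 2.95), ("C1'", "C1'", 10.44)],
    "T": [("N3", "N1", 2.82), ("O4", "N6", 2.95), ("C1'", "C1'", 10.44)],
    "G": [("O6", "N4", 2.91), ("N1", "N3", 2.95), ("N2", "O2", 2.86),
          ("C1'", "C1'", 10.44)],
    "C": [("N4", "O6", 2.91), ("N3", "N1", 2.95), ("O2", "N2", 2.86),
          ("C1'", "C1'", 10.44)],
}
COMP = {"A": "T", "T": "A", "G": "C", "C": "G"}
FLIP = np.diag([1.0, -1.0, -1.0])

def pair_transform(fwd):
    comp = COMP[fwd]
    ycoord = bases[comp]["coord"]
    ynames = bases[comp]["names"]

    def place(p):
        th, tx, ty = p
        Rz = np.array([[np.cos(th), -np.sin(th), 0],
                       [np.sin(th), np.cos(th), 0], [0, 0, 1.0]])
        return ycoord @ (Rz @ FLIP).T + np.array([tx, ty, 0.0])

    def resid(p):
        pc = place(p)
        out = []
        for na, nb, d in TARGETS[fwd]:
            a = get(fwd, na)
            b = pc[ynames.index(nb)]
            out.append(np.linalg.norm(a - b) - d)
        return out

    sol = least_squares(resid, x0=[np.pi, 6.0, -5.0])
    th, tx, ty = sol.x
    Rz = np.array([[np.cos(th), -np.sin(th), 0],
                   [np.sin(th), np.cos(th), 0], [0, 0, 1.0]])
    R = Rz @ FLIP
    t = np.array([tx, ty, 0.0])
    print(fwd, "residuals:", np.round(sol.fun, 3))
    return R, t

pairs = {b: pair_transform(b) for b in "ACGT"}

with open("R/ideal-bases-data.R", "w") as f:
    f.write("# Idealized nucleotide geometries in the glycosidic-N base frame\n")
    f.write("# (origin at N9/N1, x toward C1', z normal to the base plane) and\n")
    f.write("# Watson-Crick pair-placement transforms. Generated by\n")
    f.write("# tools/make_ideal_bases.py from chemical-component ideal geometry;\n")
    f.write("# do not edit by hand.\n\n")
    f.write(".ideal_nucleotides <- list(\n")
    ent = []
    for L in "ACGT":
        b = bases[L]
        rows = []
        nm = ", ".join('"%s"' % s for s in b["names"])
        el = ", ".join('"%s"' % s for s in b["elem"])
        ib = ", ".join("TRUE" if v else "FALSE" for v in b["is_base"])
        xyz = b["coord"]
        xs = ", ".join("%.4f" % v for v in xyz[:, 0])
        ys = ", ".join("%.4f" % v for v in xyz[:, 1])
        zs = ", ".join("%.4f" % v for v in xyz[:, 2])
        ent.append(
            '  %s = data.frame(\n    name = c(%s),\n    element = c(%s),\n'
            '    x = c(%s),\n    y = c(%s),\n    z = c(%s),\n'
            '    is_base = c(%s),\n    stringsAsFactors = FALSE)' %
            (L, nm, el, xs, ys, zs, ib))
    f.write(",\n".join(ent))
    f.write("\n)\n\n.wc_pair_transforms <- list(\n")
    ent = []
    for L in "ACGT":
        R, t = pairs[L]
        rv = ", ".join("%.8f" % v for v in R.flatten(order="F"))
        tv = ", ".join("%.8f" % v for v in t)
        ent.append('  %s = list(R = matrix(c(%s), 3, 3), t = c(%s))' % (L, rv, tv))
    f.write(",\n".join(ent))
    f.write("\n)\n")
print("wrote R/ideal-bases-data.R")
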
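"""Convert a tskit .trees file to the argtrait TSV ARG dialect.

Usage: python trees_to_tsv.py input.trees output.tsv
"""
import sys

import tskit


def main(inp, out):
    ts = tskit.load(inp)
    lines = []
    lines.append("#sequence_length")
    lines.append(repr(float(ts.sequence_length)))

    lines.append("#nodes")
    lines.append("id\ttime\tis_sample\tindividual")
    for n in ts.nodes():
        ind = "NA" if n.individual == tskit.NULL else str(n.individual)
        samp = "TRUE" if n.is_sample() else "FALSE"
        lines.append(f"{n.id}\t{repr(n.time)}\t{samp}\t{ind}")

    lines.append("#edges")
    lines.append("left\tright\tparent\tchild")
    for e in ts.edges():
        lines.append(f"{repr(e.left)}\t{repr(e.right)}\t{e.parent}\t{e.child}")

    lines.append("#sites")
    lines.append("id\tposition\tancestral_state")
    for s in ts.sites():
        lines.append(f"{s.id}\t{repr(s.position)}\t{s.ancestral_state}")

    lines.append("#mutations")
    lines.append("id\tsite\tnode\tderived_state\tparent\ttime")
    for m in ts.mutations():
        par = "NA" if m.parent == tskit.NULL else str(m.parent)
        t = "NA" if tskit.is_unknown_time(m.time) else repr(m.time)
        lines.append(f"{m.id}\t{m.site}\t{m.node}\t{m.derived_state}\t{par}\t{t}")

    lines.append("#individuals")
    lines.append("id\tnodes")
    for i in ts.individuals():
        nodes = ",".join(str(n) for n in sorted(i.nodes))
        lines.append(f"{i.id}\t{nodes if nodes else 'NA'}")

    with open(out, "w") as f:
        f.write("\n".join(lines) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
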
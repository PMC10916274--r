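/* CRC-32 (IEEE 802.3, as used by ZIP local/central headers). */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static unsigned int crc_table[256];
static int table_ready = 0;

static void make_table(void)
{
    for (unsigned int n = 0; n < 256; n++) {
        unsigned int c = n;
        for (int k = 0; k < 8; k++)
            c = (c & 1) ? 0xedb88320U ^ (c >> 1) : c >> 1;
        crc_table[n] = c;
    }
    table_ready = 1;
}

SEXP histreg_crc32(SEXP data)
{
    if (TYPEOF(data) != RAWSXP)
        error("crc32 expects a raw vector");
    if (!table_ready)
        make_table();
    const unsigned char *p = RAW(data);
    R_xlen_t n = XLENGTH(data);
    unsigned int c = 0xffffffffU;
    for (R_xlen_t i = 0; i < n; i++)
        c = crc_table[(c ^ p[i]) & 0xff] ^ (c >> 8);
    c ^= 0xffffffffU;
    return ScalarReal((double) c);
}

static const R_CallMethodDef call_methods[] = {
    {"histreg_crc32", (DL_FUNC) &histreg_crc32, 1},
    {NULL, NULL, 0}
};

void R_init_histreg(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE);
}
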
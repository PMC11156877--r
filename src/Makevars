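# Open Babel lives in the same prefix as R itself (conda-style layout);
# fall back to pkg-config when available.
OB_PREFIX = $(R_HOME)/../..
OB_CFLAGS = $(shell PKG_CONFIG_PATH=$(OB_PREFIX)/lib/pkgconfig pkg-config --cflags openbabel-3 2>/dev/null || echo -I$(OB_PREFIX)/include/openbabel3)
OB_LIBS   = $(shell PKG_CONFIG_PATH=$(OB_PREFIX)/lib/pkgconfig pkg-config --libs openbabel-3 2>/dev/null || echo -L$(OB_PREFIX)/lib -lopenbabel)

PKG_CPPFLAGS = $(OB_CFLAGS)
PKG_LIBS = $(OB_LIBS) -Wl,-rpath,$(OB_PREFIX)/lib
CXX_STD = CXX17
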